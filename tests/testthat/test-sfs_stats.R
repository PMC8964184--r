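test_that("genotype filters apply depth, missingness, heterozygosity and linkage rules", {
  # site 1: 5/10 missing (> 0.4) -> removed
  # site 2: all called genotypes heterozygous -> removed as putative paralog
  # site 3: clean
  geno <- rbind(
    c(rep(NA, 5), 0L, 1L, 2L, 0L, 1L),
    rep(1L, 10),
    c(0L, 0L, 1L, 2L, 0L, 1L, 0L, 0L, 2L, 1L)
  )
  gm <- make_gm(geno, depth = matrix(50L, 3, 10))
  out <- suppressMessages(filter_genotypes(gm, 0.4, 10L, 0.65, FALSE))
  expect_equal(n_sites(out), 1)
  expect_equal(out$sites$locus, "locus_003")
  log <- attr(out, "filter_log")
  expect_equal(unname(log["missingness"]), 1L)
  expect_equal(unname(log["heterozygosity"]), 1L)

  # low or unknown depth fails the depth filter (conservative)
  depth <- matrix(30L, 1, 4)
  depth[1, 2] <- 5L
  depth[1, 3] <- NA
  gm2 <- make_gm(matrix(c(0L, 1L, 2L, 1L), 1), depth)
  out2 <- suppressMessages(filter_genotypes(gm2, 1, 10L, 1, FALSE))
  expect_equal(unname(out2$geno[1, ]), c(0L, NA, NA, 1L))
})

test_that("one SNP per locus keeps the first SNP of each locus", {
  # 10 loci x 3 SNPs, nothing else fails -> 10 SNPs, lowest position each
  geno <- matrix(rep(c(0L, 1L, 2L, 1L), 30), nrow = 30, ncol = 4, byrow = TRUE)
  gm <- make_gm(geno, depth = matrix(50L, 30, 4),
                loci = rep(sprintf("loc%02d", 1:10), each = 3),
                pos = rep(c(20L, 5L, 11L), 10))
  out <- suppressMessages(filter_genotypes(gm, 1, 0L, 1, TRUE))
  expect_equal(n_sites(out), 10)
  expect_equal(unique(out$sites$pos), 5L)
})

test_that("allele counts tally dosages over called genotypes", {
  gm <- make_gm(rbind(c(0L, 1L, 2L), c(NA, NA, NA)))
  pm <- popmap(colnames(gm$geno), rep("p1", 3))
  ac <- allele_counts(gm, pm, "p1")
  expect_equal(ac$alt, c(3, 0))
  expect_equal(ac$called, c(6L, 0L))
  expect_error(allele_counts(gm, pm, "nope"), "not present")

  # brute-force recount on a random mixed fixture
  set.seed(42)
  geno <- matrix(sample(c(0L, 1L, 2L, NA), 200, replace = TRUE), 20, 10)
  gm2 <- make_gm(geno)
  pm2 <- make_popmap_half(gm2)
  ac2 <- allele_counts(gm2, pm2, "pop2")
  idx <- which(pm2$population == "pop2")
  for (s in seq_len(20)) {
    g <- geno[s, idx]
    expect_equal(ac2$alt[s], sum(g, na.rm = TRUE))
    expect_equal(ac2$called[s], 2 * sum(!is.na(g)))
  }
})

test_that("hypergeometric projection matches exhaustive enumeration", {
  expect_equal(project_counts(3, 6, 6), c(0, 0, 0, 1, 0, 0, 0))  # identity
  expect_equal(project_counts(0, 6, 4), c(1, 0, 0, 0, 0))        # fixed at 0
  expect_equal(project_counts(2, 4, 2), c(1, 4, 1) / 6)
  for (n in 2:8) for (np in 1:min(n, 6)) for (i in 0:n) {
    p <- project_counts(i, n, np)
    expect_equal(p, project_by_enumeration(i, n, np), tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(project_counts(1, 4, 6), "exceeds")
})

test_that("build_jsfs places projected mass and applies the call threshold", {
  # site: pop1 has 1 alt of 2 called alleles, pop2 0 of 2 -> unit mass (1,0)
  gm <- make_gm(matrix(c(1L, 0L), 1))
  pm <- popmap(colnames(gm$geno), c("pop1", "pop2"))
  sfs <- build_jsfs(gm, pm, "pop1", "pop2", 2, 2, fold = FALSE)
  expect_equal(sfs$counts[2, 1], 1)
  expect_equal(sfs_total(sfs), 1)

  # pop1 has only 2 called alleles < n1 = 4 -> site contributes nothing
  gm2 <- make_gm(matrix(c(1L, NA, 0L, 1L), 1))
  pm2 <- popmap(colnames(gm2$geno), c("pop1", "pop1", "pop2", "pop2"))
  sfs2 <- build_jsfs(gm2, pm2, "pop1", "pop2", 4, 4, fold = FALSE)
  expect_equal(sfs_total(sfs2), 0)
  expect_error(build_jsfs(gm2, pm2, "pop1", "pop1", 2, 2), "must differ")
})

test_that("build_jsfs equals the direct histogram with full data, and the
           Monte Carlo subsampling oracle with missing data", {
  set.seed(7)
  geno <- matrix(sample(c(0L, 1L, 2L), 120, TRUE, prob = c(.5, .3, .2)), 20, 6)
  gm <- make_gm(geno)
  pm <- make_popmap_half(gm)
  sfs <- build_jsfs(gm, pm, "pop1", "pop2", 6, 6, fold = FALSE)
  hist <- matrix(0, 7, 7)
  for (s in 1:20) {
    i <- sum(geno[s, 1:3]); j <- sum(geno[s, 4:6])
    hist[i + 1, j + 1] <- hist[i + 1, j + 1] + 1
  }
  hist[1, 1] <- 0; hist[7, 7] <- 0          # corners masked
  expect_equal(sfs$counts, hist)

  # with missingness: projection equals resampling alleles without replacement
  geno[sample(length(geno), 25)] <- NA
  gm <- make_gm(geno)
  sfs <- build_jsfs(gm, pm, "pop1", "pop2", 4, 4, fold = FALSE)
  ndraw <- 5000
  acc <- matrix(0, 5, 5)
  set.seed(99)
  for (s in 1:20) {
    a1 <- rep(c(1, 0), c(sum(geno[s, 1:3], na.rm = TRUE),
                         2 * sum(!is.na(geno[s, 1:3])) - sum(geno[s, 1:3], na.rm = TRUE)))
    a2 <- rep(c(1, 0), c(sum(geno[s, 4:6], na.rm = TRUE),
                         2 * sum(!is.na(geno[s, 4:6])) - sum(geno[s, 4:6], na.rm = TRUE)))
    if (length(a1) < 4 || length(a2) < 4) next
    for (d in seq_len(ndraw)) {
      i <- sum(sample(a1, 4)); j <- sum(sample(a2, 4))
      acc[i + 1, j + 1] <- acc[i + 1, j + 1] + 1
    }
  }
  acc <- acc / ndraw
  acc[1, 1] <- 0; acc[5, 5] <- 0
  # binomial MC error on ndraw draws per site; 3 SE cell-wise
  se <- sqrt(pmax(acc, 1e-4) / ndraw * 20)
  expect_true(all(abs(sfs$counts - acc) <= pmax(3 * se, 0.05)))
})

test_that("folding conserves mass, folds complements, and is idempotent", {
  set.seed(11)
  for (dims in list(c(2, 2), c(4, 2), c(5, 3), c(6, 6))) {
    counts <- matrix(rexp((dims[1] + 1) * (dims[2] + 1)), dims[1] + 1)
    sfs <- joint_sfs(counts)
    f <- fold_sfs(sfs)
    expect_equal(sfs_total(f), sfs_total(sfs), tolerance = 1e-12)
    expect_true(all(f$counts[f$mask] == 0))
    expect_warning(f2 <- fold_sfs(f), "already folded")
    expect_identical(f2$counts, f$counts)
  }
  # n1 = n2 = 2: complement of (2,1) is (0,1)
  counts <- matrix(0, 3, 3)
  counts[3, 2] <- 5  # cell (2,1)
  counts[1, 2] <- 2  # cell (0,1)
  f <- fold_sfs(joint_sfs(counts))
  expect_equal(f$counts[1, 2], 7)
  expect_true(f$mask[3, 2])
})

test_that("choose_projection maximises expected segregating sites", {
  set.seed(5)
  geno <- matrix(sample(c(0L, 1L, 2L), 60, TRUE), 10, 6)
  gm <- make_gm(geno)
  pm <- make_popmap_half(gm)
  # no missing data -> full allele counts win
  best <- choose_projection(gm, pm, c("pop1", "pop2"))
  expect_equal(c(best$n1, best$n2), c(6, 6))

  # one pop-1 individual entirely missing -> its optimum <= 2 * (3 - 1)
  geno2 <- geno; geno2[, 1] <- NA
  best2 <- choose_projection(make_gm(geno2), pm, c("pop1", "pop2"))
  expect_lte(best2$n1, 4)
  # exhaustive-scan agreement: the returned pair attains the grid maximum
  g <- best2$grid
  expect_equal(
    g$expected_segregating[g$n1 == best2$n1 & g$n2 == best2$n2],
    max(g$expected_segregating)
  )
})

test_that("diversity statistics match hand arithmetic", {
  # monomorphic matrix
  gm <- make_gm(matrix(0L, 5, 4))
  pm <- make_popmap_half(colnames(gm$geno))
  d <- diversity_stats(gm, pm)
  expect_equal(d$pi, c(0, 0))
  expect_equal(d$private_alleles, c(0L, 0L))
  expect_equal(d$pct_polymorphic, c(0, 0))

  # one site, 2 alt of 4 alleles: pi = 2 * .5 * .5 * 4/3 = 2/3
  gm2 <- make_gm(matrix(c(1L, 1L), 1))
  pm2 <- popmap(colnames(gm2$geno), c("p", "p"))
  d2 <- diversity_stats(gm2, pm2)
  expect_equal(d2$pi, 2 / 3)
  expect_equal(d2$exp_het, 0.5)
  expect_equal(d2$pct_polymorphic, 1)
  expect_equal(diversity_stats(gm2, pm2, total_sites = 100)$pi_total, (2 / 3) / 100)

  # two identical populations share all alleles -> no private alleles
  geno <- rbind(c(0L, 1L, 0L, 1L), c(2L, 1L, 2L, 1L))
  gm3 <- make_gm(geno)
  d3 <- diversity_stats(gm3, make_popmap_half(gm3))
  expect_equal(d3$private_alleles, c(0L, 0L))

  # a population with zero called sites reports NA, not zero
  geno4 <- matrix(c(NA, NA, 0L, 1L), 1)
  gm4 <- make_gm(geno4)
  d4 <- diversity_stats(gm4, make_popmap_half(gm4))
  expect_true(is.na(d4$pi[1]))
  expect_false(is.na(d4$pi[2]))

  # an allele seen in exactly one population is private to it
  geno5 <- rbind(c(2L, 2L, 1L, 2L))   # ref allele present only in pop2
  gm5 <- make_gm(geno5)
  d5 <- diversity_stats(gm5, make_popmap_half(gm5))
  expect_equal(d5$private_alleles, c(0L, 1L))
})
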