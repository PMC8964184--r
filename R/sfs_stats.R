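#' Construct a two-dimensional joint site-frequency spectrum
#'
#' Entry `(i, j)` (stored at `counts[i + 1, j + 1]`) holds the count (or
#' expectation) of sites with derived-allele count `i` in population 1 and
#' `j` in population 2. The absorbing corners `(0, 0)` and `(n1, n2)` are
#' always masked; masked cells hold 0.
#'
#' @param counts numeric matrix, `(n1 + 1) x (n2 + 1)`, non-negative.
#' @param folded logical fold state.
#' @param mask logical matrix of the same shape (`TRUE` = masked), or `NULL`.
#' @param pop1,pop2 population labels.
#' @param mask_corners mask the two absorbing corners (default `TRUE`).
#' @return An object of class `joint_sfs`.
#' @export
joint_sfs <- function(counts, folded = FALSE, mask = NULL,
                      pop1 = "pop1", pop2 = "pop2", mask_corners = TRUE) {
  counts <- as.matrix(counts)
  n1 <- nrow(counts) - 1L
  n2 <- ncol(counts) - 1L
  if (is.null(mask)) mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
  stopifnot(all(dim(mask) == dim(counts)))
  if (mask_corners) {
    mask[1L, 1L] <- TRUE
    mask[n1 + 1L, n2 + 1L] <- TRUE
  }
  counts[mask] <- 0
  if (any(counts < 0)) stop("spectrum entries must be non-negative")
  structure(
    list(counts = counts, n1 = n1, n2 = n2, folded = folded, mask = mask,
         pop1 = pop1, pop2 = pop2),
    class = "joint_sfs"
  )
}

#' @export
#' @method print joint_sfs
print.joint_sfs <- function(x, ...) {
  cat(sprintf(
    "<joint_sfs> %s, n1 = %d (%s) x n2 = %d (%s), total unmasked mass %.4g\n",
    if (x$folded) "folded" else "unfolded", x$n1, x$pop1, x$n2, x$pop2,
    sfs_total(x)
  ))
  invisible(x)
}

#' Total unmasked spectrum mass
#' @param sfs a [joint_sfs()]
#' @return numeric scalar
#' @export
sfs_total <- function(sfs) sum(sfs$counts[!sfs$mask])

#' Fold a joint spectrum onto minor-allele classes
#'
#' Cell `(i, j)` with `i + j` below `(n1 + n2)/2` receives
#' `counts[i, j] + counts[n1 - i, n2 - j]`; cells above are masked and
#' zeroed. On the boundary diagonal `i + j = (n1 + n2)/2`, self-complementary
#' cells keep their own value, and each complementary pair is summed into its
#' lexicographically smaller member. Total unmasked mass is conserved.
#' Folding a folded spectrum is a no-op (with a warning).
#'
#' @param sfs a [joint_sfs()]
#' @return A folded [joint_sfs()].
#' @export
fold_sfs <- function(sfs) {
  if (sfs$folded) {
    warning("spectrum is already folded; returning it unchanged")
    return(sfs)
  }
  n1 <- sfs$n1; n2 <- sfs$n2
  half <- (n1 + n2) / 2
  counts <- matrix(0, n1 + 1L, n2 + 1L)
  mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
  for (i in 0:n1) {
    for (j in 0:n2) {
      ii <- n1 - i; jj <- n2 - j   # complementary cell
      tot <- i + j
      if (sfs$mask[i + 1L, j + 1L] && sfs$mask[ii + 1L, jj + 1L]) {
        mask[i + 1L, j + 1L] <- TRUE
        next
      }
      v <- sfs$counts[i + 1L, j + 1L]
      w <- sfs$counts[ii + 1L, jj + 1L]
      if (tot < half) {
        counts[i + 1L, j + 1L] <- v + w
      } else if (tot > half) {
        mask[i + 1L, j + 1L] <- TRUE
      } else if (i == ii && j == jj) {      # self-complementary
        counts[i + 1L, j + 1L] <- v
      } else if (i < ii || (i == ii && j < jj)) {  # smaller member of the pair
        counts[i + 1L, j + 1L] <- v + w
      } else {
        mask[i + 1L, j + 1L] <- TRUE
      }
    }
  }
  joint_sfs(counts, folded = TRUE, mask = mask, pop1 = sfs$pop1, pop2 = sfs$pop2)
}

#' Hypergeometric down-projection of an allele count
#'
#' Probability vector over derived counts `0..n_proj` when subsampling
#' `n_proj` of `n` alleles without replacement, `i` of which are derived:
#' entry `j` equals `choose(i, j) choose(n - i, n_proj - j) / choose(n, n_proj)`.
#'
#' @param i derived-allele count, `0 <= i <= n`
#' @param n number of called alleles at the site
#' @param n_proj projected sample size, `1 <= n_proj <= n`
#' @return numeric vector of length `n_proj + 1` summing to 1.
#' @export
project_counts <- function(i, n, n_proj) {
  stopifnot(i >= 0, i <= n, n_proj >= 1)
  if (n_proj > n) stop("projection size exceeds the number of called alleles")
  dhyper(0:n_proj, m = i, n = n - i, k = n_proj)
}

#' Per-population allele counts
#'
#' @param gm a [genotype_matrix()]
#' @param popmap a [popmap()]
#' @param pop population label
#' @return data.frame with per-site `alt` (derived-allele tally) and
#'   `called` (2 x called genotypes).
#' @export
allele_counts <- function(gm, popmap, pop) {
  members <- pop_members(popmap, pop)
  missing_ids <- setdiff(members, gm$individuals)
  if (length(missing_ids))
    stop("individuals in the population map absent from the genotypes: ",
         paste(missing_ids, collapse = ", "))
  g <- gm$geno[, members, drop = FALSE]
  data.frame(
    alt = rowSums(g, na.rm = TRUE),
    called = 2L * rowSums(!is.na(g))
  )
}

#' RADseq-style genotype filtering
#'
#' Applies, in order: (a) genotypes with depth below `min_depth` or unknown
#' depth are set to missing; (b) sites with missing-genotype fraction above
#' `max_missing_frac` are removed; (c) sites with observed heterozygosity
#' among called genotypes above `max_obs_het` are removed (putative merged
#' paralogs); (d) optionally only the first (lowest-position) surviving SNP
#' per locus is kept. Counts removed at each step are reported via
#' `message()` and attached as the `"filter_log"` attribute.
#'
#' @param gm a [genotype_matrix()]
#' @param max_missing_frac maximum tolerated fraction of missing genotypes
#'   per site (default 0.40).
#' @param min_depth minimum per-genotype depth (default 10); genotypes with
#'   unknown depth fail this filter.
#' @param max_obs_het maximum observed heterozygosity per site (default 0.65).
#' @param one_snp_per_locus keep a single SNP per locus (default `TRUE`).
#' @return A filtered [genotype_matrix()]; empty output is legal (warning).
#' @export
filter_genotypes <- function(gm, max_missing_frac = 0.40, min_depth = 10L,
                             max_obs_het = 0.65, one_snp_per_locus = TRUE) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1,
            max_obs_het >= 0, max_obs_het <= 1, min_depth >= 0)
  log <- c(genotypes_zeroed = 0L, missingness = 0L, heterozygosity = 0L,
           linked_snps = 0L)

  geno <- gm$geno
  if (min_depth > 0) {
    fail <- (is.na(gm$depth) | gm$depth < min_depth) & !is.na(geno)
    log["genotypes_zeroed"] <- sum(fail)
    geno[fail] <- NA_integer_
  }
  gm <- genotype_matrix(gm$sites, geno, gm$depth, gm$individuals)

  miss <- rowMeans(is.na(gm$geno))
  keep <- miss <= max_missing_frac
  log["missingness"] <- sum(!keep)
  gm <- subset_sites(gm, keep)

  ncalled <- rowSums(!is.na(gm$geno))
  nhet <- rowSums(gm$geno == 1L, na.rm = TRUE)
  obs_het <- ifelse(ncalled > 0, nhet / ncalled, 0)
  keep <- obs_het <= max_obs_het
  log["heterozygosity"] <- sum(!keep)
  gm <- subset_sites(gm, keep)

  if (one_snp_per_locus && n_sites(gm) > 0) {
    ord <- order(match(gm$sites$locus, gm$sites$locus), gm$sites$pos)
    first <- !duplicated(gm$sites$locus[ord])
    keep <- sort(ord[first])
    log["linked_snps"] <- n_sites(gm) - length(keep)
    gm <- subset_sites(gm, keep)
  }

  message(sprintf(
    "filter_genotypes: %d genotypes set missing (depth); sites removed: %d (missingness), %d (heterozygosity), %d (one SNP per locus); %d sites retained",
    log["genotypes_zeroed"], log["missingness"], log["heterozygosity"],
    log["linked_snps"], n_sites(gm)
  ))
  if (n_sites(gm) == 0) warning("no sites survived filtering")
  attr(gm, "filter_log") <- log
  gm
}

#' Build a (folded) down-projected joint SFS from genotypes
#'
#' Each site with at least `n1` called alleles in `pop1` and `n2` in `pop2`
#' contributes the outer product of its two hypergeometric projection
#' vectors (the alternate allele playing "derived"); other sites contribute
#' nothing. Corners are masked afterwards; with `fold = TRUE` the spectrum
#' is folded onto minor-allele classes.
#'
#' @inheritParams allele_counts
#' @param pop1,pop2 distinct population labels
#' @param n1,n2 even positive projection sizes (allele counts)
#' @param fold fold the spectrum (default `TRUE`)
#' @return A [joint_sfs()].
#' @export
build_jsfs <- function(gm, popmap, pop1, pop2, n1, n2, fold = TRUE) {
  if (identical(pop1, pop2)) stop("pop1 and pop2 must differ")
  stopifnot(n1 >= 2, n2 >= 2, n1 %% 2 == 0, n2 %% 2 == 0)
  ac1 <- allele_counts(gm, popmap, pop1)
  ac2 <- allele_counts(gm, popmap, pop2)
  counts <- matrix(0, n1 + 1L, n2 + 1L)
  usable <- which(ac1$called >= n1 & ac2$called >= n2)
  for (s in usable) {
    p1 <- project_counts(ac1$alt[s], ac1$called[s], n1)
    p2 <- project_counts(ac2$alt[s], ac2$called[s], n2)
    counts <- counts + outer(p1, p2)
  }
  out <- joint_sfs(counts, folded = FALSE, pop1 = pop1, pop2 = pop2)
  if (fold) out <- fold_sfs(out)
  out
}

#' Choose projection sizes that maximise the informative spectrum
#'
#' Scans even candidate allele counts per population and returns the pair
#' maximising the expected number of segregating sites after projection
#' (sum over usable sites of one minus the probability the projected sample
#' is monomorphic). Ties are broken toward the larger total sample size.
#'
#' @inheritParams allele_counts
#' @param pops character vector of two population labels
#' @return list with `n1`, `n2`, and the scanned `grid` (data.frame).
#' @export
choose_projection <- function(gm, popmap, pops) {
  stopifnot(length(pops) == 2)
  ac1 <- allele_counts(gm, popmap, pops[1])
  ac2 <- allele_counts(gm, popmap, pops[2])
  cand1 <- seq(2L, 2L * length(pop_members(popmap, pops[1])), by = 2L)
  cand2 <- seq(2L, 2L * length(pop_members(popmap, pops[2])), by = 2L)
  grid <- expand.grid(n1 = cand1, n2 = cand2)
  grid$expected_segregating <- mapply(function(n1, n2) {
    usable <- which(ac1$called >= n1 & ac2$called >= n2)
    if (!length(usable)) return(0)
    sum(vapply(usable, function(s) {
      p1 <- project_counts(ac1$alt[s], ac1$called[s], n1)
      p2 <- project_counts(ac2$alt[s], ac2$called[s], n2)
      1 - (p1[1] * p2[1] + p1[n1 + 1L] * p2[n2 + 1L])
    }, numeric(1)))
  }, grid$n1, grid$n2)
  ord <- order(-grid$expected_segregating, -(grid$n1 + grid$n2), -grid$n1)
  best <- grid[ord[1], ]
  list(n1 = best$n1, n2 = best$n2, grid = grid)
}

#' Per-population diversity statistics
#'
#' For each population and site with `p` the alternate-allele frequency among
#' `c` called alleles: unbiased per-site nucleotide diversity
#' `2 p (1 - p) c / (c - 1)` (0 when `c < 2`), expected heterozygosity
#' `2 p (1 - p)`, a site is polymorphic when `0 < p < 1`, and an allele is
#' private when it occurs in exactly one population. `pi` is averaged over
#' variant sites by default; supply `total_sites` (e.g. all genotyped
#' positions including invariant ones) for an all-sites denominator, reported
#' alongside as `pi_total`.
#'
#' @inheritParams allele_counts
#' @param total_sites optional integer: all-sites denominator for `pi_total`.
#' @return data.frame, one row per population: `population`, `n_sites_called`,
#'   `pi`, `pi_total`, `exp_het`, `pct_polymorphic`, `private_alleles`.
#'   Populations with zero called sites get `NA` statistics.
#' @export
diversity_stats <- function(gm, popmap, total_sites = NULL) {
  unassigned <- setdiff(gm$individuals, popmap$individual)
  if (length(unassigned))
    stop("individuals without population assignment: ",
         paste(unassigned, collapse = ", "))
  pops <- unique(popmap$population)
  ac <- lapply(pops, function(p) allele_counts(gm, popmap, p))
  names(ac) <- pops

  # presence of ref / alt allele per population (for private alleles)
  has_alt <- vapply(ac, function(a) a$alt > 0, logical(n_sites(gm)))
  has_ref <- vapply(ac, function(a) a$alt < a$called, logical(n_sites(gm)))
  if (n_sites(gm) == 1) {  # vapply drops to vector
    has_alt <- matrix(has_alt, nrow = 1)
    has_ref <- matrix(has_ref, nrow = 1)
  }

  out <- lapply(seq_along(pops), function(k) {
    a <- ac[[k]]
    c_ <- a$called
    ok <- c_ >= 2
    if (!any(ok)) {
      return(data.frame(
        population = pops[k], n_sites_called = sum(c_ > 0),
        pi = NA_real_, pi_total = NA_real_, exp_het = NA_real_,
        pct_polymorphic = NA_real_, private_alleles = NA_integer_
      ))
    }
    p <- ifelse(ok, a$alt / c_, NA)
    pi_site <- ifelse(ok, 2 * p * (1 - p) * c_ / pmax(c_ - 1, 1), 0)
    eh_site <- ifelse(ok, 2 * p * (1 - p), 0)
    priv <- sum(has_alt[, k] & rowSums(has_alt) == 1) +
      sum(has_ref[, k] & rowSums(has_ref) == 1)
    data.frame(
      population = pops[k],
      n_sites_called = sum(c_ > 0),
      pi = mean(pi_site[ok]),
      pi_total = if (is.null(total_sites)) NA_real_ else sum(pi_site[ok]) / total_sites,
      exp_het = mean(eh_site[ok]),
      pct_polymorphic = mean(p[ok] > 0 & p[ok] < 1),
      private_alleles = as.integer(priv)
    )
  })
  do.call(rbind, out)
}
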