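# Small in-code fixtures shared across the suite.

# A hand-written VCF with 3 samples: two biallelic SNPs, one triallelic
# record (must be dropped), and one missing genotype.
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "indA", "indB", "indC", sep = "\t"),
    paste("locus_1", "5", ".", "A", "T", ".", "PASS", ".", "GT:DP",
          "0/1:12", "0/0:15", "1/1:9", sep = "\t"),
    paste("locus_2", "3", ".", "G", "C,A", ".", "PASS", ".", "GT:DP",
          "0/1:10", "0/2:10", "0/0:10", sep = "\t"),
    paste("locus_3", "7", ".", "C", "G", ".", "PASS", ".", "GT:DP",
          "./.:.", "0/1:20", "0/0:11", sep = "\t")
  ), path)
  path
}

# Genotype matrix built directly in code: `geno` is sites x individuals.
make_gm <- function(geno, depth = NULL, loci = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  ns <- nrow(geno)
  if (is.null(loci)) loci <- sprintf("locus_%03d", seq_len(ns))
  if (is.null(pos)) pos <- rep(1L, ns)
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("ind%02d", seq_len(ncol(geno)))
  genotype_matrix(
    data.frame(locus = loci, pos = pos, ref = "A", alt = "T",
               stringsAsFactors = FALSE),
    geno, depth, colnames(geno)
  )
}

make_popmap_half <- function(x) {
  inds <- if (inherits(x, "genotype_matrix")) x$individuals else x
  half <- length(inds) %/% 2
  popmap(inds, rep(c("pop1", "pop2"), c(half, length(inds) - half)))
}

# Independent enumeration oracle for hypergeometric down-projection:
# average the subsample spectra over every size-n_proj subset of alleles.
project_by_enumeration <- function(i, n, n_proj) {
  alleles <- c(rep(1, i), rep(0, n - i))
  subsets <- utils::combn(n, n_proj)
  out <- numeric(n_proj + 1)
  for (k in seq_len(ncol(subsets))) {
    d <- sum(alleles[subsets[, k]])
    out[d + 1] <- out[d + 1] + 1
  }
  out / ncol(subsets)
}

# Poisson-sample an observed spectrum around theta * expected.
sample_obs_sfs <- function(exp_sfs, theta, seed) {
  set.seed(seed)
  joint_sfs(
    matrix(stats::rpois(length(exp_sfs$counts), theta * exp_sfs$counts),
           nrow(exp_sfs$counts)),
    folded = exp_sfs$folded, mask = exp_sfs$mask,
    pop1 = exp_sfs$pop1, pop2 = exp_sfs$pop2, mask_corners = FALSE
  )
}
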