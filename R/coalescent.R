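#' Simulate genealogies and accumulate branch-class lengths
#'
#' Backward-time structured coalescent under an epoch schedule: within a
#' deme of size `nu(t)` every lineage pair coalesces at rate `1/nu(t)`
#' (time in `2 Nref` generations); a lineage in deme 1 moves to deme 2 at
#' backward rate `m12/2` (and deme 2 to 1 at `m21/2`), matching the scaled
#' forward convention where `m12` is migration into population 1 from
#' population 2. Exponential-size epochs are handled by analytic
#' time-rescaling inversion. Each branch accrues its length into the leaf
#' class `(i, j)` (`i` population-1 leaves, `j` population-2 leaves below it).
#'
#' @param schedule an `epoch_schedule` (from [to_epochs()] or
#'   [epoch_schedule()])
#' @param n1,n2 numbers of sampled lineages per population (`n2 = 0` allowed)
#' @param nreps number of independent genealogies
#' @param seed integer seed; the same seed and `nreps` give identical output
#' @return list with `mean` and `se` matrices (`(n1+1) x (n2+1)`) of
#'   branch-class lengths, and `nreps`.
#' @export
simulate_genealogy <- function(schedule, n1, n2, nreps = 1000L, seed = 1L) {
  stopifnot(inherits(schedule, "epoch_schedule"), n1 + n2 >= 2, nreps >= 1)
  sm <- schedule_matrix(schedule)
  if (any(sm[, c(2, 4)] <= 0, na.rm = TRUE))
    stop("epoch schedule contains a non-positive deme size")
  res <- .coal_lengths_cpp(sm, as.integer(n1), as.integer(n2),
                           as.integer(nreps), as.numeric(seed))
  mean_l <- res$sum / nreps
  var_l <- pmax(res$sumsq / nreps - mean_l^2, 0)
  list(mean = mean_l, se = sqrt(var_l / nreps), nreps = nreps)
}

#' Expected joint SFS under a demographic model (theta = 1 scale)
#'
#' Entry `(i, j)` is half the Monte Carlo mean branch-class length, so a
#' spectrum scaled by `theta` has expected count `theta * E[L(i,j)] / 2`.
#' Deterministic given `seed` (common-random-numbers contract: repeated
#' calls with the same seed and `nreps` share the underlying uniforms for
#' any parameter values).
#'
#' @param model a `demographic_model` from [model_registry()]
#' @param p named parameter vector (see [validate_params()])
#' @param n1,n2 projected allele sample sizes
#' @param nreps Monte Carlo replicates (default 50000)
#' @param seed integer seed
#' @param fold fold the expected spectrum (default `FALSE`)
#' @return A real-valued [joint_sfs()] with attribute `"se"` (per-cell Monte
#'   Carlo standard error on the theta = 1 scale).
#' @export
expected_jsfs <- function(model, p, n1, n2, nreps = 50000L, seed = 1L,
                          fold = FALSE) {
  schedule <- to_epochs(model, p)
  sim <- simulate_genealogy(schedule, n1, n2, nreps = nreps, seed = seed)
  sfs <- joint_sfs(sim$mean / 2, folded = FALSE)
  se <- sim$se / 2
  se[sfs$mask] <- 0
  if (fold) {
    folded <- fold_sfs(sfs)
    # fold sums independent MC cells; propagate variances the same way
    sev <- joint_sfs(se^2, folded = FALSE, mask_corners = FALSE)
    sev$mask <- sfs$mask
    se <- sqrt(fold_sfs(sev)$counts)
    sfs <- folded
  }
  attr(sfs, "se") <- se
  sfs
}

#' Simulate a multi-locus genotype dataset under a demographic model
#'
#' One independent genealogy per RAD locus; mutations are placed by
#' `Poisson(theta_per_locus * L_total / 2)` under infinite sites, haplotypes
#' are paired sequentially into diploid genotypes, and every SNP of a locus
#' is emitted (a downstream one-SNP-per-locus filter then exercises the real
#' pipeline). Deterministic given `seed`. Depths are left unknown;
#' [make_fixture()] adds depth and missingness.
#'
#' @inheritParams expected_jsfs
#' @param n_loci number of independent loci
#' @param n_ind1,n_ind2 diploid individuals per population
#' @param theta_per_locus scaled mutation rate `4 Nref mu L` per locus
#' @return list: `gm` (a [genotype_matrix()] of the segregating SNPs),
#'   `popmap` (a [popmap()]), `n_loci`.
#' @export
simulate_dataset <- function(model, p, n_loci, n_ind1, n_ind2,
                             theta_per_locus, seed = 1L) {
  stopifnot(n_loci >= 1, n_ind1 >= 1, n_ind2 >= 1, theta_per_locus >= 0)
  schedule <- to_epochs(model, p)
  n1 <- 2L * n_ind1
  n2 <- 2L * n_ind2
  res <- .coal_mutations_cpp(schedule_matrix(schedule), n1, n2,
                             as.integer(n_loci), theta_per_locus,
                             as.numeric(seed))
  hap <- res$hap
  nsnp <- nrow(hap)
  inds <- c(sprintf("pop1_%02d", seq_len(n_ind1)),
            sprintf("pop2_%02d", seq_len(n_ind2)))
  pm <- popmap(inds, rep(c("pop1", "pop2"), c(n_ind1, n_ind2)))
  if (nsnp == 0) {
    gm <- genotype_matrix(
      data.frame(locus = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      matrix(NA_integer_, 0, n_ind1 + n_ind2, dimnames = list(NULL, inds))
    )
    return(list(gm = gm, popmap = pm, n_loci = n_loci))
  }
  geno <- hap[, seq(1, n1 + n2, by = 2), drop = FALSE] +
    hap[, seq(2, n1 + n2, by = 2), drop = FALSE]
  colnames(geno) <- inds
  pos <- stats::ave(seq_len(nsnp), res$locus, FUN = seq_along)
  sites <- data.frame(
    locus = sprintf("locus_%05d", res$locus),
    pos = as.integer(pos),
    ref = "A", alt = "T",
    stringsAsFactors = FALSE
  )
  list(gm = genotype_matrix(sites, geno, individuals = inds),
       popmap = pm, n_loci = n_loci)
}
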