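#' Construct a genotype matrix
#'
#' The container every filter acts on: per-site biallelic diploid genotypes
#' coded as alternate-allele dosage, with per-genotype sequencing depth.
#'
#' @param sites data.frame with columns `locus` (character, one RAD locus per
#'   value), `pos` (integer, 1-based), `ref`, `alt` (single bases).
#' @param geno integer matrix, sites x individuals, values 0/1/2 or `NA`
#'   (missing genotype).
#' @param depth integer matrix of the same shape; `NA` means depth unknown.
#' @param individuals character vector of individual IDs (column order).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno, depth = NULL, individuals = colnames(geno)) {
  geno <- as.matrix(geno)
  if (is.null(depth)) depth <- matrix(NA_integer_, nrow(geno), ncol(geno))
  depth <- as.matrix(depth)
  stopifnot(nrow(sites) == nrow(geno), all(dim(geno) == dim(depth)))
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(ncol(geno)))
  stopifnot(length(individuals) == ncol(geno), !anyDuplicated(individuals))
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  sites <- as.data.frame(sites)
  stopifnot(all(c("locus", "pos", "ref", "alt") %in% names(sites)))
  rownames(geno) <- rownames(depth) <- NULL
  colnames(geno) <- colnames(depth) <- individuals
  structure(
    list(sites = sites, geno = geno, depth = depth, individuals = individuals),
    class = "genotype_matrix"
  )
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d biallelic sites x %d individuals (%d loci, %.1f%% missing)\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$sites$locus)),
    100 * mean(is.na(x$geno))
  ))
  invisible(x)
}

#' Number of sites / individuals
#' @param gm a `genotype_matrix`
#' @return integer count
#' @export
n_sites <- function(gm) nrow(gm$geno)

#' @rdname n_sites
#' @export
n_individuals <- function(gm) ncol(gm$geno)

#' Subset a genotype matrix by site index
#' @param gm a `genotype_matrix`
#' @param keep logical or integer index over sites
#' @return a `genotype_matrix`
#' @export
subset_sites <- function(gm, keep) {
  genotype_matrix(
    gm$sites[keep, , drop = FALSE],
    gm$geno[keep, , drop = FALSE],
    gm$depth[keep, , drop = FALSE],
    gm$individuals
  )
}
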