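# Self-contained synthetic fixtures: coalescent genotypes + missingness +
# Poisson sequencing depth, written as VCF + popmap + truth JSON so the
# whole pipeline can run without any external data.

#' Specify a synthetic RADseq-like fixture
#'
#' @param model_name name of a registry model (see [model_registry()])
#' @param params named true parameter vector for that model
#' @param n_loci number of independent RAD loci (default 2000, the order of
#'   magnitude of a filtered RADseq locus catalogue)
#' @param n_ind1,n_ind2 diploid individuals per population (defaults 12 and
#'   8, supporting 24/16-allele down-projection with no missing data)
#' @param theta_per_locus scaled per-locus mutation rate (default 0.2)
#' @param missing_rate independent per-genotype missingness in `[0, 1)`
#' @param mean_depth mean of the per-genotype Poisson depth (default 20)
#' @param seed integer seed
#' @return list of class `fixture_spec`
#' @export
fixture_spec <- function(model_name, params, n_loci = 2000L,
                         n_ind1 = 12L, n_ind2 = 8L, theta_per_locus = 0.2,
                         missing_rate = 0.1, mean_depth = 20,
                         seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1, mean_depth > 0,
            theta_per_locus >= 0, n_loci >= 1)
  model <- model_registry("full")[[model_name]]
  if (is.null(model)) stop("unknown model: ", model_name)
  viol <- validate_params(model, params)
  if (length(viol)) stop("invalid truth parameters: ",
                         paste(viol, collapse = "; "))
  structure(
    list(model_name = model_name, params = as.list(unlist(params)),
         n_loci = as.integer(n_loci), n_ind1 = as.integer(n_ind1),
         n_ind2 = as.integer(n_ind2), theta_per_locus = theta_per_locus,
         missing_rate = missing_rate, mean_depth = mean_depth,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Preset fixtures seeded from published best-fit island-model estimates
#'
#' Four presets, one per named model of the two pairwise comparisons, with
#' the unscaled parameter values of the corresponding best fits.
#'
#' @param ... overrides passed to [fixture_spec()] (e.g. `n_loci`, `seed`)
#' @return named list of `fixture_spec` objects
#' @export
preset_fixtures <- function(...) {
  list(
    vic_no_mig_table2 = fixture_spec(
      "vic_no_mig",
      c(nuA = 1.54, nu1 = 1.64, nu2 = 14.9, T = 0.4, s = 0.3), ...),
    founder_sec_contact_table2 = fixture_spec(
      "founder_sec_contact_asym_two_epoch",
      c(nuA = 0.43, nu1 = 10.01, nu2 = 0.36, T1 = 0.19, T2 = 0.5,
        s = 0.1, m12 = 0.23, m21 = 0.06), ...),
    founder_anc_table2 = fixture_spec(
      "founder_anc_asym_two_epoch",
      c(nuA = 0.2, nu1 = 7.24, nu2 = 0.12, T1 = 0.17, T2 = 0.02,
        s = 0.01, m12 = 1.77, m21 = 6.12), ...),
    vic_sec_contact_table2 = fixture_spec(
      "vic_sec_contact_asym_mig",
      c(nuA = 1.4, nu1 = 0.03, nu2 = 1.05, T1 = 0.43, T2 = 0.68,
        s = 0.4, m12 = 0.09, m21 = 0.05), ...)
  )
}

#' Materialise a fixture: VCF + popmap + truth JSON
#'
#' Simulates genotypes with [simulate_dataset()], injects independent
#' missingness at `missing_rate`, draws per-genotype depth from
#' `Poisson(mean_depth)` (missing genotypes get depth 0), and writes the
#' three files. Byte-identical for a given spec and seed.
#'
#' @param spec a [fixture_spec()]
#' @param outdir output directory
#' @param overwrite allow writing into an existing non-empty directory
#' @return named character vector of paths (`vcf`, `popmap`, `truth`),
#'   invisibly; the generated [genotype_matrix()] and [popmap()] are
#'   attached as attributes `"gm"` and `"popmap"`.
#' @export
make_fixture <- function(spec, outdir, overwrite = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (dir.exists(outdir) && length(dir(outdir)) && !overwrite)
    stop("output directory exists and is non-empty; use overwrite = TRUE")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  model <- model_registry("full")[[spec$model_name]]
  sim <- simulate_dataset(model, spec$params, spec$n_loci, spec$n_ind1,
                          spec$n_ind2, spec$theta_per_locus,
                          seed = spec$seed)
  gm <- sim$gm
  set.seed(spec$seed + 1L)
  geno <- gm$geno
  if (spec$missing_rate > 0 && length(geno)) {
    drop <- matrix(runif(length(geno)) < spec$missing_rate,
                   nrow(geno), ncol(geno))
    geno[drop] <- NA_integer_
  }
  depth <- matrix(rpois(length(geno), spec$mean_depth),
                  nrow(geno), ncol(geno))
  depth[is.na(geno)] <- 0L
  gm <- genotype_matrix(gm$sites, geno, depth, gm$individuals)
  paths <- c(
    vcf = file.path(outdir, "sim.vcf"),
    popmap = file.path(outdir, "popmap.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_vcf(gm, paths["vcf"])
  write_popmap(sim$popmap, paths["popmap"])
  jsonlite::write_json(unclass(spec), paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  attr(paths, "gm") <- gm
  attr(paths, "popmap") <- sim$popmap
  invisible(paths)
}
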