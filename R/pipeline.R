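# End-to-end pipeline: filter -> build SFS -> fit -> compare -> report.
# The exported functions are the package's interface; run_pipeline() wires
# them together with a single config object and a master seed.

#' Pipeline configuration
#'
#' @param vcf,popmap input paths (or `NULL` when `gm`/`pm` objects are given
#'   directly to [run_pipeline()])
#' @param pop1,pop2 population labels to compare
#' @param projection `c(n1, n2)` allele counts, or `"auto"` to let
#'   [choose_projection()] decide
#' @param fold fold the observed spectrum (default `TRUE`)
#' @param max_missing_frac,min_depth,max_obs_het,one_snp_per_locus filter
#'   thresholds (defaults 0.40 / 10 / 0.65 / `TRUE`)
#' @param registry registry tag for [model_registry()] or a model list
#' @param schema an [optim_schema()]
#' @param nreps engine replicates per likelihood evaluation
#' @param seed master integer seed (mandatory)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(vcf = NULL, popmap = NULL, pop1 = "pop1",
                            pop2 = "pop2", projection = "auto", fold = TRUE,
                            max_missing_frac = 0.40, min_depth = 10L,
                            max_obs_het = 0.65, one_snp_per_locus = TRUE,
                            registry = "full", schema = optim_schema(),
                            nreps = 50000L, seed = NULL) {
  if (is.null(seed)) stop("a master seed is mandatory")
  structure(
    list(vcf = vcf, popmap = popmap, pop1 = pop1, pop2 = pop2,
         projection = projection, fold = fold,
         max_missing_frac = max_missing_frac, min_depth = min_depth,
         max_obs_het = max_obs_het, one_snp_per_locus = one_snp_per_locus,
         registry = registry, schema = schema, nreps = nreps,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs, filter genotypes, choose/apply the projection, build
#' the folded spectrum, fit and rank every registry model, write all
#' intermediates under `outdir` (filtered-data summary, flat SFS file,
#' comparison TSV, per-model residual grids, diversity statistics, JSON log
#' with seeds and per-filter removal counts). Rerunning with the same config
#' and inputs reproduces the outputs.
#'
#' @param config a [pipeline_config()]
#' @param outdir output directory
#' @param gm,pm optional in-memory [genotype_matrix()] and [popmap()]
#'   (override the file inputs)
#' @return list: `gm_filtered`, `sfs`, `comparison`, `diversity`, `paths`.
#' @export
run_pipeline <- function(config, outdir, gm = NULL, pm = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(gm)) {
    if (is.null(config$vcf)) stop("stage input: no VCF path or genotype matrix")
    gm <- read_vcf(config$vcf)
  }
  if (is.null(pm)) {
    if (is.null(config$popmap)) stop("stage input: no popmap path or object")
    pm <- read_popmap(config$popmap)
  }

  gmf <- filter_genotypes(gm, config$max_missing_frac, config$min_depth,
                          config$max_obs_het, config$one_snp_per_locus)
  if (n_sites(gmf) == 0) stop("stage filter: no sites survived")

  if (identical(config$projection, "auto")) {
    proj <- choose_projection(gmf, pm, c(config$pop1, config$pop2))
    n1 <- proj$n1; n2 <- proj$n2
  } else {
    n1 <- config$projection[1]; n2 <- config$projection[2]
  }

  sfs <- build_jsfs(gmf, pm, config$pop1, config$pop2, n1, n2,
                    fold = config$fold)
  write_sfs_file(sfs, file.path(outdir, "observed_sfs.txt"))

  div <- diversity_stats(gmf, pm)
  write.table(div, file.path(outdir, "diversity_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  registry <- if (is.character(config$registry))
    model_registry(config$registry) else config$registry
  cmp <- compare_models(sfs, registry, schema = config$schema,
                        seed = config$seed, nreps = config$nreps)
  write_fit_table(cmp, file.path(outdir, "model_comparison.tsv"))

  for (nm in names(cmp$fits)) {
    f <- cmp$fits[[nm]]
    exp_sfs <- expected_jsfs(f$model, f$params, sfs$n1, sfs$n2,
                             nreps = config$nreps,
                             seed = (config$seed * 1000003) %% 2147483647,
                             fold = TRUE)
    res <- sfs_residuals(sfs, exp_sfs, f$theta_hat)
    write.table(res, file.path(outdir, paste0("residuals_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }

  log <- list(
    seed = config$seed, n1 = n1, n2 = n2, fold = config$fold,
    filters = as.list(attr(gmf, "filter_log")),
    sites_in = n_sites(gm), sites_used = n_sites(gmf),
    nreps = config$nreps,
    package_version = as.character(utils::packageVersion("twopopsfs"))
  )
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  list(gm_filtered = gmf, sfs = sfs, comparison = cmp, diversity = div,
       paths = dir(outdir, full.names = TRUE))
}
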