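#' Read biallelic SNPs from a VCF file
#'
#' Keeps only biallelic SNP records (single-base REF and ALT). Genotypes are
#' coded as alternate-allele dosage 0/1/2 (`NA` when missing); per-genotype
#' depth is taken from the DP FORMAT field when present, otherwise marked
#' unknown. The CHROM field is the RAD-locus ID (one locus per CHROM string),
#' POS the 1-based site position.
#'
#' @param path path to a VCF v4.x file (plain text or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "."
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  alleles <- gsub("\\|", "/", gt)
  dosage[alleles %in% c("0/0")] <- 0L
  dosage[alleles %in% c("0/1", "1/0")] <- 1L
  dosage[alleles %in% c("1/1")] <- 2L
  dp <- matrix(NA_integer_, nrow(gt), ncol(gt))
  fmt <- vcf@gt[keep, 1, drop = TRUE]
  if (any(grepl("DP", fmt, fixed = TRUE))) {
    dpc <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
    )
    dp[] <- as.integer(round(dpc))
  }
  dp[is.na(dosage)] <- NA_integer_  # depth is irrelevant for missing calls
  sites <- data.frame(
    locus = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    stringsAsFactors = FALSE
  )
  genotype_matrix(sites, dosage, dp, colnames(gt))
}

#' Write a genotype matrix as VCF v4.2
#'
#' @param gm a [genotype_matrix()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=twopopsfs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (i in seq_len(n_sites(gm))) {
    g <- gm$geno[i, ]
    d <- gm$depth[i, ]
    cells <- ifelse(
      is.na(g), "./.:.",
      paste0(gt_code[g + 1L], ":", ifelse(is.na(d), ".", d))
    )
    writeLines(paste(c(
      gm$sites$locus[i], gm$sites$pos[i], ".", gm$sites$ref[i],
      gm$sites$alt[i], ".", "PASS", ".", "GT:DP", cells
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write a population map
#'
#' A population map is a two-column tab-separated file without header:
#' individual ID, population label.
#'
#' @param path file path
#' @return data.frame with columns `individual`, `population`.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("individual", "population"))
  popmap(pm$individual, pm$population)
}

#' @rdname read_popmap
#' @param popmap data.frame as returned by [popmap()]
#' @export
write_popmap <- function(popmap, path) {
  write.table(popmap, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a population map
#'
#' @param individual character vector of unique individual IDs
#' @param population character vector of non-empty population labels
#' @return data.frame of class `popmap`
#' @export
popmap <- function(individual, population) {
  individual <- as.character(individual)
  population <- as.character(population)
  stopifnot(length(individual) == length(population))
  if (anyDuplicated(individual)) stop("individual IDs must be unique")
  if (any(!nzchar(population))) stop("population labels must be non-empty")
  structure(
    data.frame(individual = individual, population = population,
               stringsAsFactors = FALSE),
    class = c("popmap", "data.frame")
  )
}

pop_members <- function(popmap, pop) {
  if (!pop %in% popmap$population)
    stop(sprintf("population '%s' not present in the population map", pop))
  popmap$individual[popmap$population == pop]
}

#' Write a joint SFS to a flat text file
#'
#' Uses the conventional flat spectrum dialect: line 1 holds the dimensions,
#' fold state and quoted population labels
#' (`"<n1+1> <n2+1> folded \"pop1\" \"pop2\""`), line 2 the row-major entries
#' (population-1 index slowest), line 3 the row-major mask (1 = masked).
#'
#' @param sfs a [joint_sfs()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_sfs_file <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    '%d %d %s "%s" "%s"', sfs$n1 + 1L, sfs$n2 + 1L,
    if (sfs$folded) "folded" else "unfolded", sfs$pop1, sfs$pop2
  ), con)
  writeLines(paste(format(as.vector(t(sfs$counts)), trim = TRUE, digits = 17),
                   collapse = " "), con)
  writeLines(paste(as.integer(as.vector(t(sfs$mask))), collapse = " "), con)
  invisible(path)
}

#' @rdname write_sfs_file
#' @export
read_sfs_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("SFS file must have 3 non-empty lines")
  head <- scan(text = lines[1], what = character(), quiet = TRUE)
  if (length(head) < 3) stop("malformed SFS header line")
  d1 <- as.integer(head[1]); d2 <- as.integer(head[2])
  folded <- identical(head[3], "folded")
  if (!folded && !identical(head[3], "unfolded"))
    stop("SFS header fold state must be 'folded' or 'unfolded'")
  pops <- if (length(head) >= 5) head[4:5] else c("pop1", "pop2")
  vals <- scan(text = lines[2], what = numeric(), quiet = TRUE)
  msk <- scan(text = lines[3], what = integer(), quiet = TRUE)
  if (length(vals) != d1 * d2 || length(msk) != d1 * d2)
    stop("SFS entry/mask count does not match declared dimensions")
  counts <- matrix(vals, nrow = d1, ncol = d2, byrow = TRUE)
  mask <- matrix(msk == 1L, nrow = d1, ncol = d2, byrow = TRUE)
  joint_sfs(counts, folded = folded, mask = mask, pop1 = pops[1], pop2 = pops[2],
            mask_corners = FALSE)
}

#' Write a model-comparison table
#'
#' Tab-separated, one row per fitted model sorted by AIC ascending, with
#' columns `model`, `loglik`, `k`, `AIC`, `deltaAIC`, `weight`, then one
#' column per free parameter (blank when a model lacks that parameter).
#'
#' @param cmp a model comparison from [compare_models()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(cmp, path) {
  tab <- as.data.frame(cmp)
  tab[is.na(tab)] <- ""
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
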