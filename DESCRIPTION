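Package: twopopsfs
Title: Two-Population Demographic Model Selection from the Joint Site
    Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two-population demographic histories
    (vicariance versus founder events, with or without gene flow) from
    reduced-representation SNP data. Reads biallelic SNP genotypes from VCF,
    applies depth, missingness and heterozygosity filters, builds folded and
    down-projected two-dimensional joint site-frequency spectra, computes
    per-population diversity statistics, evaluates expected spectra under
    epoch-structured island models with a structured-coalescent Monte Carlo
    engine, fits models by Poisson composite likelihood with profiled theta,
    and ranks them by AIC, delta-AIC and Akaike weights. Includes a coalescent
    simulator of synthetic RADseq-like datasets with configurable missingness
    and sequencing depth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
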