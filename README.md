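# twopopsfs

Demographic model selection for two populations from the joint
site-frequency spectrum (JSFS), aimed at phylogeographers working with
RADseq-style SNP data who want to distinguish **vicariance** from **founder
events** — with or without gene flow — between two groups of populations.

## What it does

The pipeline turns a VCF of biallelic SNPs plus a population map into a
folded, down-projected two-dimensional JSFS — the matrix `S[i, j]` counting
SNPs with minor-allele count *i* in population 1 and *j* in population 2 —
and fits a candidate set of eight epoch-structured "island" models by
Poisson composite likelihood,

```
log L(p, θ) = Σ_ij [ S_ij log(θ M_ij(p)) − θ M_ij(p) − log S_ij! ]
```

where `M(p)` is the expected spectrum at θ = 1 under parameter vector
`p = (nuA, nu1, nu2, T or T1/T2, s, m12, m21)` and θ = 4·N_ref·μ·L is
profiled analytically. Expected spectra come from a structured-coalescent
Monte Carlo engine (Rcpp) that accumulates expected branch lengths per
frequency class under any backward-time epoch schedule — population splits,
founding fractions `s ≤ 0.5`, two-epoch and exponential size trajectories,
and asymmetric migration switched on per epoch. Models are ranked by
`AIC = 2k − 2 log L`, ΔAIC and Akaike weights `ω_i`.

A coalescent simulator of synthetic RADseq-like datasets (independent loci,
per-locus θ, missing genotypes, Poisson sequencing depth) makes the whole
pipeline runnable and testable with no external data.

## Worked example

Simulate a dataset from the vicariance-no-migration preset (true values
nuA = 1.54, nu1 = 1.64, nu2 = 14.9, T = 0.4, s = 0.3), run it through the
standard filters, build the folded spectrum and compare two models:

```r
library(twopopsfs)

spec  <- preset_fixtures(n_loci = 1500L, seed = 42)$vic_no_mig_table2
paths <- make_fixture(spec, "fx")
gm  <- read_vcf(paths[["vcf"]])
pm  <- read_popmap(paths[["popmap"]])
gmf <- filter_genotypes(gm)   # max 40% missing, min depth 10x, max obs het 0.65
#> filter_genotypes: 269 genotypes set missing (depth); sites removed: 0
#> (missingness), 18 (heterozygosity), 1880 (one SNP per locus); 1285 sites retained

proj <- choose_projection(gmf, pm, c("pop1", "pop2"))   # -> 16, 12 alleles
sfs  <- build_jsfs(gmf, pm, "pop1", "pop2", proj$n1, proj$n2, fold = TRUE)
#> <joint_sfs> folded, n1 = 16 (pop1) x n2 = 12 (pop2), total unmasked mass 1067

reg    <- model_registry("full")[c("vic_no_mig", "founder_sec_contact_asym_two_epoch")]
schema <- optim_schema(replicates = c(150, 6, 3), fold = c(3, 2, 1.3),
                       maxit = c(1, 50, 80), nreps_frac = c(0.1, 0.3, 1))
compare_models(sfs, reg, schema = schema, seed = 7, nreps = 5000)
#> <sfs_model_comparison>
#>                                model    loglik k      AIC deltaAIC weight
#> 1                         vic_no_mig -172.2155 5 354.4310   0.0000 0.9559
#> 2 founder_sec_contact_asym_two_epoch -172.2917 8 360.5834   6.1524 0.0441
#>       nuA     nu1     nu2      T     T1     T2      s    m12   m21
#> 1  0.2951  0.3374  2.0990 0.0873     NA     NA 0.2927     NA    NA
#> 2 10.3929 12.1937 75.4044     NA 0.0077 2.9212 0.0875 0.0016 2e-04
```

The true (vicariance) model wins with 96% of the Akaike weight: the richer
founder model matches the data about equally well (it nests a
vicariance-like history at T1 → 0, m → 0) but pays the 2·(8 − 5) AIC
penalty. Fitted parameters are reported on the likelihood's scale ridge —
only ratios are identified once θ is profiled (note nu2/nu1 ≈ 6.2 against
the true 14.9/1.64 ≈ 9.1); `canonical_params()` rescales a fit to a known
reference θ when absolute values are needed. `diversity_stats()` adds
Table-1-style per-population summaries (π, expected heterozygosity,
% polymorphic sites, private alleles), and `run_pipeline()` wires all
stages together behind a single config with one master seed.

See the vignette (`vignettes/demographic-model-selection.Rmd`) for the
model definitions, engine design, numerical choices and limitations.

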