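---
title: "Two-population demographic model selection from the joint SFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-population demographic model selection from the joint SFS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Given biallelic SNP genotypes from two groups of populations — typically a
reduced-representation (RADseq) dataset of hundreds to thousands of
independent loci — we want to decide how the two groups came to be
separate: an old *vicariance* (a formerly continuous population split into
comparably sized fractions), an old *founder event* (a small fraction of
the ancestral population founding a derived "island" population), or a
recent founder event; each optionally with gene flow that was continuous,
ancestral-then-isolated, or restricted to a recent secondary contact.

The sufficient statistic used throughout is the two-dimensional joint
site-frequency spectrum (2D-JSFS): the matrix whose entry \((i, j)\) counts
SNPs with derived-allele count \(i\) in population 1 and \(j\) in
population 2. Because ancestral states are unknown for typical RADseq data,
spectra are *folded* onto minor-allele classes, and because genotypes are
missing at random across individuals, allele counts are *down-projected*
hypergeometrically to a smaller, fixed sample size per population.

## From VCF to a folded, projected spectrum

`read_vcf()` keeps biallelic SNP records, coding genotypes as
alternate-allele dosage with per-genotype depth (DP). `filter_genotypes()`
applies the standard RADseq hygiene in a fixed, logged order:

1. genotypes with depth below 10x (or unknown depth) are set to missing —
   unverifiable depth cannot pass a depth filter;
2. sites with more than 40% missing genotypes are removed;
3. sites with observed heterozygosity above 0.65 are removed, the usual
   guard against merged paralogs;
4. one SNP (the first by position) is kept per RAD locus, so cells of the
   spectrum can be treated as independent.

The thresholds are arguments; those defaults match common practice for
PstI single-digest RAD data. The order is fixed so removal counts are
reproducible; each run logs them.

`project_counts(i, n, n_proj)` is the hypergeometric redistribution
\(P(j) = \binom{i}{j}\binom{n-i}{n'-j}/\binom{n}{n'}\); `build_jsfs()` adds
the outer product of the two per-population projection vectors for every
site with at least `n1` and `n2` called alleles, then masks the absorbing
corners \((0,0)\) and \((n_1,n_2)\). `choose_projection()` scans all even
candidate sizes and keeps the pair maximising the expected number of
segregating sites after projection — the usual trade-off between sample
size and site retention under missing data; ties go to the larger sample.

Folding merges \((i,j)\) with its complement \((n_1-i, n_2-j)\). On the
boundary diagonal \(i+j = (n_1+n_2)/2\) the complement pairing would
double-count, so self-complementary cells keep their own value and each
pair is summed into its lexicographically smaller member; total unmasked
mass is conserved and folding is idempotent.

## The candidate models

All models share one forward skeleton: an ancestral population of size
`nuA` (all sizes are ratios to an implicit reference size \(N_{ref}\);
times are in units of \(2N_{ref}\) generations) splits at time `T` (or
`T1 + T2`) into population 1 with fraction \(1-s\) and the derived
population 2 with fraction `s`, bounded at \(s \le 0.5\). Size
trajectories are `constant` (sizes jump to `nu1`, `nu2` at the split),
`two_epoch` (founding sizes for `T1`, then `nu1`, `nu2` for `T2`) or
`exp_growth` (exponential interpolation from the founding sizes to the
present sizes). Migration `m12` is the scaled rate \(2N_{ref}m\) *into*
population 1 *from* population 2, switched on per epoch according to the
migration mode.

```{r}
library(twopopsfs)
model_registry("full")
```

Four of the eight candidates reproduce named, published model structures
(`vic_no_mig`, `vic_sec_contact_asym_mig`,
`founder_sec_contact_asym_two_epoch`, `founder_anc_asym_two_epoch`, with
k = 5, 8, 8, 8 free parameters). The remaining four complete the scenario
x growth x migration grid — `founder_no_mig_exp`,
`founder_continuous_asym_mig_exp`, and the two recent-founder variants.
This completion is this package's own choice of a balanced grid, not a
reproduction of any published supplementary set. "Recent founder" is the
founder topology with the split-time upper bound reduced an order of
magnitude (to 0.05), encoding the pre-/post-glacial distinction by time
rather than by a different likelihood form. In the constant-size models
`s` does not enter the epoch schedule (daughter sizes jump straight to
`nu1`, `nu2`), so it is statistically inert there; it is kept as a free,
bounded parameter to preserve the published parameter counts.

Two design points resolved here: the first epoch of two-epoch founder
models is *fixed* at the founding sizes `nuA(1-s)`, `nuA*s` (the fewest
parameters consistent with k = 8), and `nuA` is free in every model.

## The coalescent engine

Expected spectra are computed by structured-coalescent Monte Carlo rather
than a diffusion PDE solver. Each model renders to a backward-time epoch
schedule (`to_epochs()`); within a deme of size \(\nu(t)\) each lineage
pair coalesces at rate \(1/\nu(t)\), lineages migrate backward at per-lineage
rate \(m/2\), and exponential-size epochs are handled by analytic inversion
of the cumulative coalescent hazard. Every branch accrues its length into
the leaf class \((i, j)\); the expected spectrum at \(\theta = 1\) is
\(E[\xi_{ij}] = E[L_{ij}]/2\), which in the single-deme constant-size limit
reproduces \(\theta/i\) exactly (this is a test).

Replicates use independent, reproducible random streams (one xoshiro256++
stream per replicate, seeded by SplitMix64 from the user seed), so a given
seed and replicate count define a *common-random-numbers* surface: the
same uniforms underlie every parameter evaluation inside one fit, making
the composite likelihood a deterministic function of the parameters and
letting the simplex search converge despite Monte Carlo noise.

`simulate_dataset()` reuses the same engine per locus, placing
\(\mathrm{Poisson}(\theta_{locus} L_{tot}/2)\) mutations on branches under
infinite sites and pairing haplotypes sequentially into diploids — the
generative counterpart of the expectation, which is exactly what the
end-to-end self-consistency test verifies.

## Fitting and ranking

The objective is the Poisson composite likelihood over unmasked cells,
with \(\theta\) profiled analytically at every evaluation
(\(\hat\theta\) = observed mass / model mass). Optimization follows the
multi-round perturbation style common in SFS pipelines: round 1 draws
starting points log-uniformly within bounds, later rounds perturb the
incumbent best log-uniformly within a shrinking fold, and each replicate
runs a Nelder-Mead local search in an unconstrained space mapped to the
bounds by a log-scale logistic transform (so \(s \le 0.5\) can never be
crossed). The default schema is four rounds of 10/20/30/40 replicates with
folds 3/2/2/1 and iteration caps 30/40/50/60; a schema can also declare a
round with `maxit <= 1` as a pure screening round, and per-round fractions
of the engine replicate budget, which is how the validation suites buy
hundreds of cheap starts before refining (their exact settings live in the
test code and are deliberately smaller than the defaults so the suites run
in minutes on one core).

Two numerical choices matter:

* **Monte Carlo zeros.** An expected cell the engine never visited is not
  an impossible class, only one below the engine's resolution (~1/nreps).
  Inside the fit objective such cells are floored at half a replicate unit
  (0.5/nreps) so an observed count there is penalised at the resolution
  scale instead of the hard floor of 1e-300 that `poisson_loglik()` itself
  applies. Without this, fits of histories with near-empty cells become
  jagged and optimization stalls.
* **The scale ridge.** With \(\theta\) profiled, the likelihood is exactly
  invariant under sizes and times \(\times c\), migration \(/c\),
  \(\theta/c\): only ratios are identified. The convention here pegs
  nothing, so fitted parameter vectors are points on that ridge.
  `canonical_params()` rescales a fit to a reference \(\theta\) — for
  simulated data the generator's known \(\theta\) — making parameters
  absolute. Parameter-recovery validation is performed after this
  rescaling; the model ranking (AIC, weights) is unaffected by the ridge.

Models are ranked by \(AIC = 2k - 2\log L\) with \(k\) excluding the
profiled \(\theta\) — the convention that reproduces published AIC margins
from published log-likelihoods — then \(\Delta AIC\) and Akaike weights
\(\omega_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}\) over the full fitted
set.

## The synthetic-data generator

`fixture_spec()` / `make_fixture()` produce VCF + popmap + truth-JSON
fixtures with the statistical structure the analysis assumes: independent
loci, one genealogy per locus, configurable per-locus \(\theta\)
(default 0.2, giving on the order of one SNP per retained locus),
12 + 8 diploid individuals (supporting the 24/16-allele projections used
throughout validation), independent per-genotype missingness (default
10%) and Poisson sequencing depth (default mean 20x, so the 10x filter
removes a realistic minority of genotypes). `preset_fixtures()` ships four
presets whose true parameters are published best-fit estimates for the
four named models.

What the generator does *not* emulate: linked SNPs beyond shared
genealogies within a locus, allele dropout and PCR duplicates,
population-structured missingness, sequencing error, and reference bias.
Passing tests therefore demonstrate internal correctness of the statistics
and the inference machinery under the model's own assumptions, not
robustness to those artefacts in real RADseq data.

## Validation design and problem sizes

The suite validates, at desk scale on one core:

* printed-arithmetic identities (AIC margins from published
  log-likelihoods; the eight-model registry; the s bound);
* analytic limits (single-population \(\theta/i\) at \(2\times10^5\)
  replicates; pairwise coalescence times; fold conservation; projection
  against exhaustive enumeration for all \(n \le 8\));
* end-to-end self-consistency (3,000 simulated loci at an 8x6 projection
  against a \(2\times10^5\)-replicate expectation, cell-wise within 3
  Monte Carlo standard errors computed from per-locus contributions);
* parameter recovery for the four presets (spectra of ~5,000 SNPs at
  \(\theta = 500\), 24x16 projection, 3 seeds each, engine budget
  \(10^4\) replicates per evaluation) with median relative error
  thresholds of 30% for sizes and 50% for times after canonical
  rescaling;
* model discrimination (vicariance truth versus a founder alternative,
  10 seeds at a 12x8 projection).

## Known limitations

* Composite likelihood treats spectrum cells as independent; it is valid
  for point estimation and AIC-style ranking, not for exact uncertainty —
  no bootstrap or Godambe correction is provided.
* Time-partition parameters of secondary-contact histories are weakly
  identified when migration is weak: with scaled rates below ~0.1 the
  expected number of migration events carries almost no information on
  when contact started, and the composite-likelihood optimum for `T1`/`T2`
  can sit far from the truth even at 5,000 SNPs (sizes remain well
  recovered). The recovery suite shows exactly this for the
  vicariance-with-secondary-contact preset, whose printed migration rates
  are 0.09 and 0.05.
* The engine supports at most 64 haplotypes in mutation mode (bitmask
  leaf sets); expected spectra have no such limit in practice.
* Absolute parameter values require an external \(\theta\) reference
  (see the scale ridge above); only ratios are data-identified.
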