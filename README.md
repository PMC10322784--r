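# duplexmut

Analysis toolkit for **duplex-sequencing mutagenicity studies** in rodent
models: error-corrected sequencing over a targeted panel yields per-animal
somatic variant calls at mutation frequencies around 1e-7 per bp, and the
questions are the classic ones of genetic toxicology — does the test
article increase the mutation frequency, at which dose, with what mutation
spectrum, and how should such a study be designed?

The package covers the full path from post-consensus variant tables to
regulatory-style endpoints:

- **Clonality-aware mutation frequencies.** Identical mutations within one
  animal may descend from a single mutational event that expanded
  clonally. Counting each distinct mutation once gives the conservative
  *MF_Min* = unique mutations / duplex bp; counting every duplex source
  molecule gives *MF_Max* = total mutations / duplex bp. Calls with
  variant allele fraction > 0.01 are removed as germline before either.
- **Dose-response statistics.** Group mutation frequencies are estimated
  by a binomial-logit GLM with dose as a factor and Pearson-based
  dispersion (R's quasibinomial), back-transformed with delta-method
  standard errors; treated-vs-control contrasts are tested two-sided and
  Holm-Sidak adjusted. Per-target analyses use a binomial GLMM with a
  per-animal random intercept (`lme4`), including pooling of targets by
  genic/intergenic location.
- **Mutation spectra and signatures.** Six-class, nine-class (SNV classes
  plus mnv/ins/del) and 96-trinucleotide spectra in COSMIC ordering;
  heterogeneity across dose groups by a depth-aware G-test with
  Monte-Carlo null; cosine similarity against a user-supplied COSMIC SBS
  catalogue and ranking of signatures by their dose-vs-control similarity
  shift.
- **Benchmark-dose modeling.** The BMD for a 50% increase over background
  (BMR = 0.5) via four mean-curve families (exponential, reverse
  exponential, Hill, lognormal-CDF) fit by maximum likelihood, AIC-based
  Akaike weights, log-scale model averaging, and a 200-replicate
  parametric bootstrap for the 95% confidence interval.
- **Power and study design.** A Monte-Carlo simulator of two-group duplex
  experiments — per-animal counts are
  `Binomial(depth, plogis(qlogis(MF * fold) + eps))` with a logit-scale
  animal effect `eps ~ N(0, sd)` — tested with the same quasibinomial
  contrast, plus minimum-detectable-effect-size (MDES) estimation by
  bisection and sample-size x sequencing-depth power sweeps.
- **Synthetic cohorts.** `simulate_panel()` / `simulate_study()` generate
  complete cohorts (per-sample VCFs, depth/design tables, reporter-assay
  plaque counts) with configurable clonal expansion and dose-dependent
  spectrum shifts, so every stage is testable without any sequencing
  download.

## Worked example

A fully synthetic study at the default conditions (4 dose groups x 6
animals, background MF 1.31e-7, 7.98e8 duplex bp/animal):

```r
library(duplexmut)

panel  <- simulate_panel(seed = 1)                 # 20 x 2.4 kb targets
study  <- simulate_study(study_config(seed = 1), panel)
calls  <- filter_germline(study$calls)             # drops VAF > 0.01
#> filter_germline: removed 120 call(s) with VAF > 0.01

tallies    <- tally_cohort(calls, study$depth, panel, study$design)
per_sample <- panel_tally(tallies)
dose <- study$design$dose[match(per_sample$sample_id, study$design$sample_id)]

fit_dose_glm(per_sample$unique_mutations, per_sample$duplex_bp, dose)
#>    dose estimate      sem fold fold_sem    p_raw    p_adj
#> 1  0.00 1.31e-07 7.77e-09 1.00    0.000       NA       NA
#> 2  6.25 1.69e-07 8.83e-09 1.29    0.102 3.93e-03 3.93e-03
#> 3 12.50 2.14e-07 9.93e-09 1.64    0.123 2.24e-06 4.49e-06
#> 4 25.00 3.31e-07 1.23e-08 2.53    0.177 2.36e-11 7.07e-11
```

Each row is one dose group: the model-based mutation frequency (per bp)
with its SEM, the fold change over vehicle control, and the raw and
Holm-Sidak-adjusted p-values of the treated-vs-control contrast — a
significant, dose-dependent increase at every dose, recovering the
generator's programmed folds (1.26 / 1.55 / 2.46).

```r
gt <- group_tallies(per_sample, study$design)
model_average_bmd(data.frame(dose = gt$dose, count = gt$unique_mutations,
                             denom = gt$duplex_bp), seed = 1)
#> model-averaged BMD (BMR = 50% increase): 10 [7.21, 12.4] (ok)
#> Akaike weights:
#>         exponential reverse_exponential                hill           lognormal
#>               0.578               0.047               0.194               0.181
```

The dose producing a 50% MF increase over background is about 10
mg/kg-bw/day, with a bootstrap 95% CI of roughly 7-12.

```r
estimate_power(power_scenario(n_per_group = 3, fold = 1.5,
                              n_sims = 2000, seed = 1))
#> power 0.907 (MC SE 0.006) for fold 1.5, n = 3/group
mdes(power_scenario(n_per_group = 3, n_sims = 2000, seed = 1))
#> MDES 1.404-fold at 80% power (n = 3/group)
```

Three animals per group retain ~91% power to detect a 1.5-fold MF
increase at the default depth, and the smallest fold detectable with 80%
power is about 1.40.

`run_pipeline()` chains all stages (tallies, estimates, per-target mixed
models, spectra, signature ranking, BMD, optional power section) from a
single YAML or list configuration and writes seed-stamped TSVs plus a
manifest; `inst/scripts/run_pipeline.R` wraps it for shell use.

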