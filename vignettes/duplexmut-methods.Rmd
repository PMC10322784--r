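---
title: "Models and methods behind duplexmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind duplexmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmut)
```

This vignette explains the statistical models in `duplexmut`, the choices
made where several reasonable implementations existed, and what the
synthetic-data tests do and do not demonstrate about real data.

## The measurement model

Duplex sequencing reads both strands of each source DNA molecule and
calls a mutation only when the strands agree, which pushes the error
floor below typical somatic mutation frequencies (~1e-7 per bp in rodent
bone marrow). The unit of observation is one animal: a set of somatic
variant calls over a targeted panel, plus the number of duplex base pairs
sequenced (the denominator). Two frequencies bracket the truth when a
mutation is observed in several molecules of one animal:

* **MF_Min** counts each distinct `(chromosome, position, ref, alt)` once
  per animal: all copies are assumed to descend from one mutational event
  that expanded clonally.
* **MF_Max** counts every supporting duplex molecule: each copy is
  assumed an independent event.

Identity of a mutation is evaluated *within* one animal only — the
clonal-expansion argument does not extend across animals, so identical
calls in different animals are never collapsed. Multi-nucleotide variants
and indels count as single events. Calls with variant allele fraction
above 0.01 are excluded as germline before any tally (strictly greater:
a call at exactly 0.01 is kept).

Internally, intervals live in `GRanges`/`IRanges` (1-based, closed), the
Bioconductor convention; BED input and output is converted at the file
boundary. This delegates all interval arithmetic to IRanges rather than
maintaining a second coordinate convention inside the package.

## Dose-response estimation

Group frequencies are estimated with a binomial-logit GLM with dose as a
factor, with the dispersion estimated from Pearson residuals — exactly
R's `quasibinomial` family. Group means are back-transformed from the
logit scale; standard errors follow by the delta method
(`se(p) = se(eta) * p(1-p)`), and fold changes versus the vehicle control
carry delta-method SEs that use the full coefficient covariance.
Treated-vs-control contrasts use the model's t statistics on the
residual degrees of freedom — the same inference `summary.glm()` reports
for quasi-families — and are two-sided. The family of treated-vs-control
p-values within one endpoint is adjusted by the step-down Sidak (Holm-
Sidak) procedure: with p-values sorted ascending,
`adj_i = max_{j<=i} (1 - (1 - p_j)^(m-j+1))`.

The choice of t-based rather than normal-based inference matters at
small group sizes: with three animals per group the contrast has four
residual degrees of freedom, and a z test would overstate significance
substantially. The package's power simulations (below) reproduce the
reference power table only under t-based inference, which is also what
standard R tooling produces.

A dose group with zero events would have an infinite logit; for
estimation only, half an event and one trial are added to such a group
and the result is flagged. This situation does not arise at realistic
duplex depths.

Per-target estimates use a binomial GLMM
(`events/denominator ~ dose + (1 | animal)`, Laplace approximation via
`lme4::glmer`). With one observation per animal per target the random
intercept acts as an observation-level effect absorbing between-animal
overdispersion. Contrasts are z-based Wald tests, the convention for
mixed-model output. Non-convergence is reported in the result object
rather than raised, so a screen across twenty targets degrades
gracefully. Note one practical consequence of the Laplace fit: even when
data are generated with zero animal variance, the fitted variance is a
small positive number and fixed effects match the plain GLM only to a
few hundredths on the logit scale, not to machine precision.

Targets can be pooled by their genic/intergenic annotation
(`pool_by = "genic"`), fitting dose x location fixed effects — the
standard way to ask whether transcribed regions, subject to
transcription-coupled repair, respond less than intergenic ones.

## Spectrum comparison

Subtype composition across dose groups is compared with a
likelihood-ratio G statistic against expected counts that allocate each
subtype's pooled total to groups proportionally to group sequencing
depth. With all expected cells at least 5 the asymptotic chi-square with
`(groups-1)(subtypes-1)` degrees of freedom is used; otherwise the null
distribution is simulated by multinomial resampling of the table
conditional on the grand total, with cell probabilities equal to depth
share times pooled subtype rate. The literature's "modified contingency"
procedures for mutant counts with unequal denominators admit several
algebraic variants; this realization was chosen because it reduces
exactly to the classical G-test at equal depths and its Monte-Carlo
branch is valid at any count size. Per-subtype dose-vs-control
comparisons reuse the quasibinomial machinery on each subtype's counts
over depth, Holm-Sidak adjusted across subtypes within a dose.

Trinucleotide (SBS96) spectra read the flanking bases from the panel
reference; purine-reference sites are reverse-complemented, context and
alleles together, into the pyrimidine-reference COSMIC ordering. SNVs at
the first or last base of a target have no context and are excluded with
a warning and a count. Signature comparison uses cosine similarity on
raw panel spectra — no renormalization by genome-to-panel trinucleotide
abundance is applied by default, appropriate when the panel's
composition tracks the genome's; signatures are ranked by the difference
between their similarity to an exposed group's spectrum and to the
control spectrum.

## Benchmark-dose modeling

The benchmark dose is the dose at which the fitted mean frequency
reaches 1.5x background (BMR = 0.5, the convention for genotoxicity
endpoints). Four mean-curve families are fit on the frequency scale by
maximizing the binomial likelihood, with parameters transformed so the
optimizer works unconstrained:

| family | mean function | parameters |
|---|---|---|
| exponential | `a exp(b d^c)` | `a, b > 0`, `c > 0` |
| reverse exponential | `a (m - (m-1) exp(-b d))` | asymptote `a m` |
| Hill | `a (1 + (m-1) d^c / (k^c + d^c))` | half-max dose `k` |
| lognormal | `a (1 + (m-1) Phi(log(d/k)/s))` | lognormal-CDF sigmoid |

Each fit tries several starting points around moment-based initial
values. The BMD is closed-form for the exponential family
(`(log(1+BMR)/b)^(1/c)`) and found by bracketed root finding elsewhere
(relative tolerance 1e-8). A family whose fitted curve cannot reach the
benchmark within 10x the largest observed dose is flagged `unbounded`
— saturating fits below 1.5-fold, and essentially flat dose-responses,
therefore produce no BMD rather than an extrapolated one.

Converged families receive Akaike weights `w_i ∝ exp(-ΔAIC_i/2)`. The
point estimate is the weighted *geometric* mean of per-family BMDs:
BMDs are ratio-scale quantities, so averaging on the log scale is the
coherent choice (and matches how BMD confidence bounds are usually
displayed, on log-dose axes). The 95% CI comes from a parametric
bootstrap (default 200 replicates): counts are resampled from the
model-averaged curve using a normal approximation to the overdispersed
binomial with the Pearson dispersion of the best full-data fit held
fixed, all families are refit, one family is drawn per replicate with
probability equal to its Akaike weight, and the 2.5/97.5 percentiles of
the replicate BMDs are reported. A case bootstrap (resampling animals)
is not the default because BMD datasets are often group-aggregated.
When more than half the replicates fail to produce a BMD the result is
flagged `unstable`.

## The power simulator

The study-design simulator asks: with `n` animals per group, `D` duplex
bp per animal and between-animal spread `s`, what is the probability of
detecting a given fold increase? Per animal,

```
eps   ~ Normal(0, s)                 (logit scale)
count ~ Binomial(D, plogis(qlogis(MF0 * fold) + eps))
```

and each simulated two-group experiment is tested with the quasibinomial
GLM contrast above: success means two-sided p < 0.05 *and* an estimated
increase. Defaults mirror the reference study's observed conditions:
`MF0 = 1.31e-7`, `D = 7.98e8`, `s = 0.062` (the between-animal SD of the
logit-scale intercept estimated by the per-target mixed model; 0.1
represents a roughly doubled variance). The multiplicative scale of the
animal effect means `s` is, to first order at rare frequencies, the
coefficient of variation it adds to per-animal counts. Applying it on
the logit scale keeps the simulator consistent with the binomial-logit
models used for inference. At these parameters the simulator reproduces
the reference design table: ~92% power for a 1.5-fold increase at
n = 3, >95% at n = 6, ~49% at the low-dose fold of 1.26, ~81% at a
reduced depth of 5e8 bp, and ~77-78% at n = 4, 3e8 bp, s = 0.1.

The two-group test inside the simulation loop is evaluated in closed
form (saturated two-parameter logit model: pooled group frequencies,
Pearson dispersion, Fisher information), which the test suite verifies
against `glm()` to numerical accuracy; 10,000 simulated experiments run
in well under a second.

The **minimum detectable effect size** is found by bisecting the power
curve over folds in [1.01, 5] until the bracket is narrower than 0.01
fold. Every power evaluation reuses the same seed (common random
numbers), making the empirical power curve monotone in fold so the
bisection cannot be derailed by Monte-Carlo noise; the default 2000
simulations per evaluation put about one point of MC standard error on
each power estimate near 80%.

## The synthetic-cohort generator

`simulate_study()` emulates post-consensus variant tables, not reads: no
sequencing error, UMI handling or consensus miscalls are modeled. Per
animal, one logit-scale effect `eps` is shared across all targets (a
true animal effect, inducing the positive covariance between targets
that the GLMM exploits), and per-target unique-mutation counts are
binomial at depth split proportionally to target width. Each unique
mutation receives:

* a position drawn without collision, interior to the target;
* a class (`snv`/`mnv`/`ins`/`del`, default 0.85/0.05/0.02/0.08 —
  substitutions dominate, deletions outnumber insertions, as observed in
  this tissue);
* for SNVs, a subtype from the dose's six-class spectrum placed on a
  compatible reference base (complemented when landing on a purine);
* a clonal multiplicity: with probability `clonal_fraction(dose)` the
  event is expanded to `2 + Geometric(0.5)` copies (mean two extra),
  otherwise multiplicity 1;
* a VAF equal to multiplicity over site-level duplex coverage
  (depth/width), which lands far below the 0.01 germline threshold.

A configurable number of germline-like calls with VAF in (0.3, 0.6) is
planted per sample to exercise the filter. Default folds
(1 / 1.26 / 1.55 / 2.46), clonal fractions (0.040 / 0.121 / 0.186 /
0.251) and spectra interpolating from a background dominated by C>A and
C>G toward an exposure profile with 29% T>C, 28% C>T and 13% T>A were
chosen so the generated cohort's group summaries match the reference
study's reported group means; the clonal fractions solve
`excess = unique x fraction x mean_clone_extra` for the reported group
excesses of 50/198/351/770 mutations. The dose dependence of clonality
is a free parameter, not a fitted law — the data only establish that it
increases with dose.

What passing tests on synthetic cohorts show: the estimators recover the
parameters the generator encodes (folds, spectra, overdispersion,
benchmark doses) at realistic counts, and the pipeline's plumbing is
correct end-to-end. What they cannot show: robustness to panel-specific
artifacts (homologous or repetitive targets, alignment error), germline
contamination structure beyond a VAF threshold, clone-size distributions
unlike the geometric, or depth imbalance across targets beyond
proportional splitting.

## Numerical and reproducibility choices

* Problem sizes in the test suite: power checks at 2000-10,000
  simulations (about one point of MC standard error, or half that, near
  80% power), MDES at 2000 per bisection step, BMD bootstrap at 20-100
  replicates in tests and 200 by default in analyses, cohort generation
  at the full 24-animal default design. These sizes make the suite's
  stochastic assertions reproducible at fixed seeds while keeping a full
  run to a few minutes.
* All stochastic entry points (`simulate_study`, `simulate_lacz`,
  `estimate_power`, `mdes`, `model_average_bmd`,
  `spectrum_difference_test`) take explicit seeds; identical seed and
  configuration reproduce outputs byte-for-byte, and `run_pipeline()`
  stamps every output file with the seed and writes a config hash into
  its manifest.
* Ties in signature ranking are broken by signature label; spectra built
  from zero mutations return zero proportions rather than NaN; empty
  panels, single-dose designs, all-zero subtype rows and zero-variance
  correlation inputs raise immediate, named errors.
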