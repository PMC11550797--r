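---
title: "Sparse Bayesian detection of drug–ADR associations under polypharmacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse Bayesian detection of drug–ADR associations under polypharmacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why sparse shrinkage for pharmacovigilance

Emergency-department cohorts of adverse drug reactions (ADRs) are
high-dimensional by construction: each case carries the full medication
list (often 5–15 drugs from a universe of well over a thousand
substances), outcomes such as falls are rare, and only a handful of drugs
plausibly drive any given ADR. Fitting one logistic model per drug ignores
co-medication; fitting an unpenalized joint model with hundreds of binary
indicators and a rare outcome overfits or fails to converge. `adrsignal`
fits the joint model under global-local shrinkage priors so that noise
coefficients collapse towards zero while genuinely large effects escape
shrinkage, and then reads off signals from posterior credible intervals.

This vignette documents the model, the calibration rules and defaults, the
synthetic-data generator and its realism limits, the numerical choices,
and the known limitations. Everything quantitative stated here is computed
by the package's test suite or by `scripts/acceptance.R`.

## Model

For case $i$, outcome $y_i \in \{0, 1\}$ (the ADR of interest vs any other
ADR) and predictors $x_i$:

$$y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 + x_i^\top\beta)).$$

The predictor block is: one binary indicator per selected drug, then age
(years), female sex (female = 1), the number of drugs excluded from the
analysis for that case, and eight drug–drug-interaction covariates — the
per-case counts of CYP3A4, CYP2D6, CYP2C19 and CYP2C9 substrates and
inhibitors. Predictors enter **unstandardized** (binary indicators and
small counts are already on comparable scales, and age-per-year effects
remain directly interpretable); this is configurable only by transforming
the design yourself, and is a deliberate, documented choice.

### Regularized horseshoe prior

$$\beta_j \sim \mathcal{N}(0, \tau^2\tilde\lambda_j^2), \quad
\tilde\lambda_j^2 = \frac{c^2\lambda_j^2}{c^2 + \tau^2\lambda_j^2}, \quad
\lambda_j \sim \mathrm{C}^+(0,1), \quad
\tau \sim \mathrm{C}^+(0,\tau_0), \quad
c^2 \sim \mathrm{Inv\text{-}Gamma}\!\left(\tfrac{\nu}{2}, \tfrac{\nu s^2}{2}\right).$$

Small $\tau\lambda_j$ gives near-complete shrinkage; large $\lambda_j$
lets $\beta_j$ escape, but the slab width $c$ bounds how far
($\tilde\lambda_j \to c/\tau$). Two formulas calibrate the prior to the
data dimensions:

* **Global scale** `compute_global_scale(p0, p, n)`:
  $\tau_0 = \frac{p_0/(p-p_0)}{\sqrt n}$, the ratio of the expected number
  of nonzero coefficients $p_0$ to expected zeros, damped by the root
  sample size. At $p_0 = 5$, $p = 100$, $n = 7175$ this gives
  $\tau_0 \approx 6.21\times10^{-4}$ — aggressive shrinkage.
* **Slab scale** `compute_slab_scale(c0, p0, sd_y)`:
  $s = \sqrt{c_0/p_0}\,\mathrm{sd}(y)$. The outcome standard deviation is
  the *population* form $\sqrt{q(1-q)}$ of the binary outcome (the $n$ vs
  $n-1$ convention is not identifiable from any description of the method;
  we fix the population form and document it).

Defaults, with units and rationale:

| parameter | default | meaning |
| --- | --- | --- |
| `p0` | 5 (announced loudly) | expected number of truly associated predictors; the one knob an analyst should set deliberately |
| `slab_constant` $c_0$ | 31.25 | makes $s = 2.5\,\mathrm{sd}(y)$ at the default `p0`, a weakly informative slab on the log-odds scale |
| `slab_df` $\nu$ | 4 | light-tailed slab, standard for the regularized horseshoe |
| intercept prior | $\mathcal{N}(0, 10^2)$ | wide; the intercept is excluded from shrinkage |

### Laplace (Bayesian lasso) prior

$\beta_j \sim \mathrm{Laplace}(0, b)$ with fixed, user-settable scale
$b = 1$ by default. The scale is *not* adapted to the data; see
Limitations for the consequences.

## Inference engine

Sampling is by Pólya-Gamma data augmentation: given auxiliary
$\omega_i \sim \mathrm{PG}(1, \eta_i)$, the conditional for
$(\beta_0, \beta)$ is exactly multivariate normal, drawn by Cholesky
factorization of the $(p+1)\times(p+1)$ conditional precision. The PG
variates use the alternating-series rejection sampler (exact, no
truncation error). Horseshoe latents $\log\lambda_j$, $\log\tau$ and
$\log c^2$ are updated by univariate stepping-out slice sampling
(tuning-free, always accepts); the lasso mixture variances are conjugate
inverse-Gaussian updates. All randomness flows through R's RNG, so a
single seed reproduces every chain; chains run sequentially with
deterministically derived per-chain seeds, and generator functions restore
the caller's RNG state.

Correctness is established two independent ways in the test suite:

* the unnormalized log posterior (`log_unnorm_posterior()`) is checked
  against a separately coded density, and the sampler's 1-predictor
  marginals against a 2-D grid-quadrature oracle that integrates the local
  scale out through the substitution $u = \tfrac{2}{\pi}\arctan\lambda$;
* a predictor column of all zeros has a flat likelihood, so its posterior
  must reproduce the prior marginal — verified by Kolmogorov–Smirnov tests
  against exact ancestral prior draws (horseshoe) and the analytic Laplace
  CDF.

Convergence is monitored by split-R-hat and an effective-sample-size
estimate (Geyer initial monotone sequence) per coefficient. A fit whose
worst R-hat exceeds `rhat_max` (default 1.01) or worst ESS falls below
`ess_min` (default 400) carries `converged = FALSE`, raises a warning, and
propagates exit status 2 through the pipeline manifest — deliberately
strict defaults; short exploratory chains will be flagged.

## Signal classification

Equal-tailed credible intervals use quantile interpolation between order
statistics (R's default type 7); the convention is fixed because displayed
interval endpoints must be reproducible. A coefficient is **light
positive** if its 50% interval lies entirely above zero and **strong
positive** if the 90% interval does too (mirrored for negative). An
endpoint exactly at zero counts as covering zero — the conservative
reading of a rounded "0.00" bound. Signal tables list drugs before
covariates, strong before light classes, descending median within class.
Negative classifications are reported but must not be read as protective
effects: in an all-ADR cohort the control group consists of *other* ADRs,
so drugs prevalent among stable patients or among the control ADRs appear
negative as an artifact.

## The synthetic-data generator

No public ADR polypharmacy cohort of this shape exists, so the generator
is a first-class module with known ground truth. It emulates:

* **Drug popularity skew**: Zipf weights $r^{-1.5}$ over the catalog. The
  exponent was calibrated once so that, on the benchmark fixture, the
  median number of excluded (non-top-100) drugs per case is 1 (IQR 0–2)
  while >100 substances clear the 32-case frequency threshold; the
  mid-rank exposure curve recovers the exponent within a few percent by
  log-log regression.
* **Drugs per case**: negative binomial (mean 7.8, dispersion 2.5),
  truncated to ≥1, sampled without replacement within a case — curated
  median 7, IQR ≈ (4, 11).
* **Age**: skew-normal (location 91, scale 29, shape −5) truncated to
  [18, 105] years — median ≈ 72, IQR ≈ (58, 81).
* **Visit structure**: a configurable number of patients receive exactly
  one second visit (more than two visits were never needed for the
  curation logic being exercised); missing medication is an empty drug
  list, not a sentinel string.
* **Catalog structure**: configurable fractions of combination products
  ("a/b" from two plain components), unspecific names, supplements, and
  independent per-enzyme CYP substrate/inhibitor flags.
* **Outcomes**: Bernoulli draws from a sparse logistic ground-truth model
  whose predictors are computed by the same curation annotators used for
  analysis.

The benchmark fixture (`fixture_cohort()`) pins the data-flow arithmetic:
7967 raw cases, 791 repeat visits, 1 missing-medication case, a
1627-substance catalog, hence exactly 7175 analysis cases and a
7175 × 112 design (100 drug indicators + 11 covariates + outcome; the
case identifier is carried separately — the 112 accounting is documented
here because it is a convention, not a law). Outcome labels are drawn so
that *exactly* 455 (fall variant) or 1977 (bleeding variant) of the
survivors are positive, by sampling positives without replacement with
probability proportional to each case's odds under the planted model —
exact counts and recoverable signals at the same time.

What the generator does **not** emulate — and therefore what passing
tests do *not* establish about real data: co-prescription correlation
structure beyond shared popularity (real anticoagulant/antiplatelet
clusters are strongly correlated), confounding by indication (a drug
prescribed *because of* early outcome symptoms), dose, duration,
MedDRA-coded outcome ascertainment, or site effects. Parameter-recovery
results on synthetic cohorts are a necessary sanity check of the
machinery, not evidence about any specific clinical association.

## Curation pipeline choices

Stage order is fixed: first-visit filter → missing-medication exclusion →
name normalization → frequency selection → covariates → assembly. Other
choices made where the procedure was genuinely open:

* The frequency threshold is 32 by default; `min_count = "auto"`
  formalizes "the optimum between fewest coefficients and highest total
  exposure" as the threshold maximizing (cumulative-exposure coverage
  fraction) − (retained-drug fraction), a knee criterion on the frequency
  curve; diagnostics expose the whole curve.
* Combination names split on "/" except for a configurable keep-main map
  (amoxicillin/clavulanic acid → amoxicillin, oxycodone/naloxone →
  oxycodone, tilidine/naloxone → tilidine by default, where the partner
  component only potentiates the main substance).
* Frequency ties break alphabetically; matrix rows are in ascending
  case-id order; drugs absent from the CYP table contribute zero to all
  CYP counts; sex is coded female = 1.
* Per-case excluded-drug counts include unspecific/supplement names
  removed during normalization, so (selected indicators) + (excluded) =
  (normalized medication list size) holds for every case.

## Problem sizes used by the bundled checks

The test-suite and acceptance-script runs use deliberately modest sizes
chosen to exercise every code path at desk scale: the full 7967-case
fixture for the curation arithmetic; $n = 50$, $p = 1$ for the quadrature
oracle (where quadrature is exact to grid resolution); and $n = 4000$,
$p = 100$ with five planted effects of log-odds 1.0–2.0 (on drugs at
observed frequency ranks 3, 8, 15, 25, 40, spanning common to uncommon
exposure), 2 chains × (300 warmup + 400 draws), seeds 201–205, for
parameter recovery. These are the package's reference conditions; larger
runs only tighten the Monte Carlo error.

## Limitations

* **Fixed-scale lasso over-flags well-identified nulls.** With a fixed
  Laplace scale $b$, the posterior for a truly null coefficient with
  standard error $se$ is approximately normal around a soft-thresholded
  estimate shifted only by $se^2/b$; as information grows the 50%
  interval excludes zero with probability approaching 50%. On the
  recovery benchmark the lasso therefore flags dozens of the 95 null
  drugs where the horseshoe flags at most a handful — the same
  qualitative contrast seen when both priors are applied to real ADR
  data (the lasso is the less aggressive shrinker and flags roughly twice
  as many predictors), but sharper. The package reports this honestly:
  the lasso half of the bundled recovery check fails by design of the
  prior, and the shrinkage-ordering check (lasso flags ≥ horseshoe flags)
  passes. An adaptive scale (hyperprior on $b$) would fix it and is out
  of scope here, where $b$ is deliberately a fixed, user-settable
  constant.
* The 50%/90% thresholds are conventions, not error rates; no
  multiple-testing adjustment is applied, and coefficients are reported
  on the raw log-odds scale, not as odds ratios.
* Negative signals are not interpretable as protection (see above).
* The strict default diagnostics (R-hat ≤ 1.01, ESS ≥ 400) flag most
  short chains; treat flagged fits as exploratory.
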