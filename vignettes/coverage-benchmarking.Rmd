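---
title: "Methods: district-level coverage estimation and benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: district-level coverage estimation and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
three-stage small-area model, the covariate completion model, the
preprocessing rules, what the synthetic-data generator does and does not
emulate, and the numerical and design choices a maintainer would want
written down.

## 1. Setting and assumptions

The estimand is the coverage p ∈ (0, 1) of a health intervention in every
district and year of a study window (by default 72 districts in 9
provinces, 1990–2010). Data are sparse and heterogeneous: survey-based
district-year point estimates with design-based sampling variances,
administrative program counts, and census-anchored population denominators.
The model assumes:

* observations are unbiased for the district-year coverage, with known
  (reported) sampling variance — multiple sources for the same cell may
  disagree within their stated noise;
* coverage evolves smoothly in time within a district, and districts within
  a province share part of their deviation from the covariate-driven mean;
* covariates enter as point values (their own estimation uncertainty is not
  propagated — the same simplification the underlying study makes).

## 2. The three-stage estimator

**Stage 1 (mean model).** Unweighted OLS of logit-transformed observations
on the centred year, six socio-demographic covariates, and the indicator's
own province-level series (proportion scale). One coefficient vector per
indicator. Unweighted is the default because the reported sampling
variances are themselves noisy for small samples; `fit_stage1(weighted =
TRUE)` provides the precision-weighted variant. Rank-deficient designs drop
collinear columns with a warning rather than failing.

**Stage 2 (spatial-temporal smoothing).** Residuals are smoothed to every
cell by a separable weight: spatial factor 1 (same district), ζ (same
province), 0 (elsewhere); temporal factor tricube,
w(Δt) = (1 − (|Δt|/(λ+1))³)³ for |Δt| ≤ λ. Cells with no in-support
residuals keep the stage-1 prediction. Defaults λ = 10 years, ζ = 0.5: the
mean function should borrow strength broadly; the GP stage, not the
smoother, is responsible for tracking local wiggles.

**Stage 3 (Gaussian process).** Conditional on the stage-2 mean surface,
districts are independent GPs over years with Matérn covariance. Defaults:
ν = 3/2; amplitude σ estimated per indicator as the standard deviation of
the observation residuals around the stage-2 surface, floored at 0.1 logit
units (the prior must never collapse); length-scale ρ = 3 years. The
length-scale was the one genuinely open kernel choice: at ρ ≈ 10 the
kernel's lag-1 correlation is ≈ 0.99 — a nearly constant process over a
21-year window, unable to follow scale-up-era deviations of a few years'
duration; ρ = 3 matches the few-year persistence of district-level program
fluctuations, and the simulation calibration test (Section 6) validates
the choice under the default scenario. Observation noise is the logit-space
sampling variance; multiple sources in one district-year enter as separate
observations, never pre-averaged. Posterior draws (default 1,000) are taken
per district in logit space and inverse-logit transformed; summaries are
the draw mean and the 2.5th/97.5th percentiles with the
linear-interpolation percentile rule (`stats::quantile` type 7).

```{r}
library(covbench)
study <- simulate_study(seed = 1)
fit <- estimate_study(study, st = st_config(lambda = 10, zeta = 0.5),
                      gpr = gpr_config(rho = 3, nu = 3/2, n_draws = 1000),
                      seed = 1)
```

## 3. Preprocessing rules

* **Boundary offset.** eps = 1e-4, so the smallest representable coverage
  equals the 0.01% pre-launch floor exactly; `to_logit()` clamps to
  [eps, 1 − eps] and propagates variances by the delta method,
  var_logit = var_p / (p(1−p))².
* **Degenerate proportions.** An observed 0 or 1 from a finite sample
  reports zero design-based variance. Treating that as near-exact would pin
  the GP to the boundary, so such records get the binomial logit-information
  variance 1/(n p\*(1−p\*)) at the continuity-corrected proportion
  p\* = (n p̂ + 0.5)/(n + 1) — weakly informative, as an all-success sample
  of 20 should be. Zero-variance records *without* a finite sample size
  (exact/limit records, floor records carry their own variance) fall back
  to the logit-variance floor of 0.001, which exists because the GP needs
  strictly positive noise. In the zero-noise end-to-end experiment the
  floor is set commensurately small (1e-8), since there it is the only
  noise in the system.
* **Pre-launch floors.** Coverage of 0.0001 is assumed for every
  district-year strictly before an indicator's floor year (malaria-type
  1997, pentavalent-type 2004), with a small fixed logit-space variance
  (0.01). Observed pre-launch records are overridden by default — the
  assumption is a blanket one; `override = FALSE` fills only missing cells.
  The operation is idempotent.
* **District splits.** Pre-2000 observations refer to the old, coarser
  geography. Harmonization multiplies each parent record by the inheritor's
  reference ratio r_d — the mean over reference-window years (2000–2010) of
  the inheritor's estimate over the share-weighted parent-level estimate —
  clipping to [0, 0.99] with a warning and inflating the variance by 1.5.
  The mean-of-yearly-ratios statistic (not ratio of means) keeps r_d
  share-consistent: the share-weighted mean of adjusted inheritors
  reproduces the parent estimate exactly when nothing is clipped.
* **Administrative spray data.** Coverage = structures sprayed divided by
  geometrically interpolated household counts, capped at 0.99 (reported
  numerators can exceed census denominators), with a fixed logit-space
  variance of 0.1 because administrative sources carry no design-based
  variance.
* **Households/population interpolation.** Log-linear (geometric)
  interpolation between census anchors, nearest-segment extrapolation
  outside; anchors are reproduced exactly.

## 4. Covariate completion

Each covariate is completed independently on a transformed scale — logit
for proportions, log for household size, identity (floored at 0) for years
of education — by (i) a linear mixed model on a natural cubic spline in
year with one interior knot at 2000 and district random intercepts and
slopes, fitted by REML with ML fallback and a fixed-effects-only fallback
when the random effects are inestimable (fewer than three districts,
singular fits); and (ii) a per-district GP around the stage-(i) curve with
the same Matérn family as the indicator model. Health-facility density is
time-constant (a single observation year) and bypasses completion.
Province-level indicator series — the Ind_{k,t} covariate — are produced by
precision-weighted aggregation of district observations to provinces
followed by the same two-step model, so province-only records (surveys
without district identifiers) still contribute.

## 5. The synthetic-data generator

The generator defines the study conditions for every simulation-based test.
Truth is constructed *from* the stage-1 functional form — a known
coefficient vector on known covariate surfaces plus the province indicator
series — plus smooth AR(1) shocks (lag-1 correlation 0.8) at province (SD
0.15) and district (SD 0.3) level in logit space, so coefficient recovery
is well-posed and the residual structure matches what stages 2–3 assume.
Scenario defaults mirror the study's qualitative patterns: 12 indicators —
four malaria-control interventions launched in 1997 scaling up through a
logistic province curve, pentavalent vaccine launched 2004, BCG/measles
high and stable, polio/ANC4/SBA stagnating or declining, exclusive
breastfeeding rising. Intercepts are anchored so a reference district sits
at a stated typical level (e.g. ANC4 at 55% in 2000, declining). Surveys
follow a realistic cadence (periodic multi-source plans, effective
district samples of ~100 split across up to five retrospective
birth-years, design effect 1.5), observations are binomial at the
effective size with design-effect-inflated variances, pre-2000 records are
re-expressed on the old geography, and administrative spray counts carry
mean-one lognormal noise (CV 0.2).

What the generator does **not** emulate: indicator-specific biology,
correlated non-sampling error between sources, survey weighting artifacts,
real district names or calendars, or covariate measurement error that
correlates with outcomes. A passing calibration test therefore shows the
estimator is correct *under its own assumptions* — honest noise,
unbiased sources — not that real surveys satisfy them.

## 6. Validation by simulation

The test suite computes, among others:

* exact recovery of all nine stage-1 coefficients on noiseless saturated
  data, checked against a normal-equations oracle;
* agreement of the GP posterior (mean and covariance) with an explicit
  dense-solve oracle on every district;
* empirical coverage of the 95% UI over 50 simulation replicates of the
  default scenario (12 indicators × 72 districts × 21 years, 200 draws per
  replicate for speed — the draw count only affects Monte-Carlo error of
  the summaries);
* the accuracy ordering MAE(stage 3) ≤ MAE(stage 1 + ST) ≤ MAE(stage 1)
  averaged over 20 replicates;
* conservation identities (composite of all-100% components is exactly
  100%; equal-population national equals the simple mean; split
  harmonization conserves parent-level coverage absent clipping);
* byte-identical draws under a repeated seed; and the zero-noise
  end-to-end identity.

These runs condition on the true covariate surfaces and true province
series: the covariate completion model is validated separately (parameter
recovery of the random-effect scale, closed-form GP checks), and the study
design itself treats covariates as plug-in values, so indicator-model
calibration is the question of interest. Replicate sizes (50 for
calibration, 20 for the accuracy ordering) keep Monte-Carlo error on a
coverage proportion below about one percentage point while the whole suite
stays comfortably runnable on a laptop.

## 7. Numerical choices

* Jitter: Cholesky factorizations are attempted exactly first; on failure a
  diagonal jitter starts at 1e-8 and multiplies by 10 up to 1e-2 before
  erroring with the district named. This keeps the GP equal to its dense
  oracle whenever the system is well-posed.
* Draws are clamped to [1e-15, 1 − 1e-15] after the inverse logit so the
  draw cube is strictly inside (0, 1) even when a posterior mean underflows.
* Range-gap ties break by district id order; "decline" means a strictly
  negative point-estimate change, with significance-aware counts (draw-level
  95% interval entirely below zero) reported alongside.
* The composite divides by the identically-accumulated weight sum so an
  all-equal basket reproduces its common value exactly in floating point.
* Seeds: every generator and the draw stage take explicit seeds; internal
  streams are derived deterministically, and the caller's RNG state is
  restored afterwards.

## 8. Design decisions on open points

* **SES composite**: the four socio-demographic components (adult
  education, improved sanitation, improved cooking fuel, electricity) are
  standardized to zero mean and unit variance across district-years and
  averaged with equal weights; a first-principal-component variant was
  deliberately left out of scope. Zero-variance components are excluded
  with a warning (score 0 when nothing varies).
* **Composite-vs-SES correlation**: pooled across all district-years by
  default (per-year pooling is available by subsetting), since the pooled
  Pearson statistic is the reproducible interpretation of a correlation
  "across districts and years".
* **Province aggregation weights**: inverse-variance with a variance floor;
  population-share weighting is the fallback when no variances are usable.
* **National uncertainty**: aggregation is draw-by-draw, so national UIs
  inherit the within-draw correlation of districts rather than assuming
  independence.
* **Floors override observed pre-launch data** by default, reading the
  0.01% assumption as a blanket one; both behaviors are implemented.

## 9. Limitations

Per-district GPs ignore residual spatial correlation beyond what stage 2
absorbs; kernel hyperparameters are fixed defaults, not optimized by
marginal likelihood; delta-method variances degrade near the boundary
(mitigated, not removed, by the degenerate-cell rule); harmonization
ratios assume the reference-period proportional relationship extends back
in time; and calibration statements are conditional on the generator's
assumptions listed in Section 5.
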