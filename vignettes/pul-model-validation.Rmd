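---
title: "Validating two-hCG triage models for pregnancy of unknown location"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating two-hCG triage models for pregnancy of unknown location}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

A woman presenting with pain or bleeding in early pregnancy whose pregnancy
cannot be located on transvaginal ultrasound has a *pregnancy of unknown
location* (PUL). Most PUL resolve spontaneously (failed PUL) or turn out to
be intrauterine pregnancies (IUP); a minority are ectopic pregnancies (EP),
which can rupture and are the outcome triage must not miss. The change in
serum hCG between two samples drawn roughly 48 hours apart carries most of
the diagnostic signal: falling hCG suggests a failed PUL, doubling suggests
a viable IUP, and a plateau raises concern for EP. Persisting PUL (PPUL),
defined by a plateau of at least three consecutive hCG values each changing
by less than 15% within a week, are managed as ectopics and grouped with EP
throughout (`dichotomize_outcome()`, `adjudicate_ppul()`).

## The prediction model and its evaluation

The model family supported here is a three-class multinomial logistic
regression with failed PUL as the reference class and linear predictors
built from natural-log transforms of the first hCG and of the hCG ratio
(second/first), including quadratic and interaction terms. Probabilities
come from a softmax over `(0, eta_iup, eta_ep)`; the row maximum is
subtracted before exponentiation so that extreme logits neither overflow
nor produce `NaN`, and the three probabilities sum to one to within 1e-12.

Coefficients are deliberately **not** hard-coded. A model is a JSON
configuration (`read_model_spec()`) naming its basis terms and
coefficients; unknown keys and unknown basis names are load-time errors so
a transcription typo cannot silently evaluate as a zero coefficient. The
package ships two *synthetic placeholder* configurations
(`example_model()`) whose structure matches the published two-hCG model
family but whose coefficients are invented; validating the real published
models requires transcribing their equations into such a configuration.
All downstream machinery is coefficient-agnostic.

A record is classified high risk of EP when its predicted EP probability
*reaches* the threshold (`p_ep >= t`, boundary inclusive). Argmax outcome
labels break exact ties in the fixed order failed PUL, IUP, EP, purely so
results are deterministic; ties have probability zero in practice.

## The validation battery

**Discrimination.** The AUC is computed by the Mann–Whitney identity using
midranks (ties count one half), in O(n log n); the O(n²) pairwise count is
retained in the test suite as an oracle. Sampling variance uses the DeLong
structural-components construction, `var(V10)/n1 + var(V01)/n0`, and the
paired test for two models scored on the same records uses the paired
component covariances with a two-sided normal reference. Confidence
intervals are Wald on the AUC scale, truncated to [0, 1]; a logit-scale
interval would be an alternative near the boundaries, but the symmetric
interval matches how such validations are conventionally reported. Under
perfect separation the variance estimate is exactly zero; the result is
flagged degenerate rather than silently reported.

**Calibration.** Calibration-in-the-large is the intercept of a binomial
GLM of the outcome on an offset of `logit(p)` with slope fixed at 1
(positive values mean the model under-predicts on average); the
calibration slope comes from the unconstrained recalibration
`y ~ a + b*logit(p)`. Both are IRLS fits (`stats::glm`) with convergence
tolerance 1e-10 and at most 100 iterations — far tighter than reporting
precision. Probabilities are clipped to [1e-12, 1 − 1e-12] before the
logit, since softmax outputs can underflow. Complete separation is detected
from the fitted-probability warnings of the IRLS fit and raised as an
error instead of returning a diverged coefficient. With constant `p` the
offset-model MLE has the closed form `logit(observed rate) − logit(p)`,
which the tests check to 1e-8.

**Calibration curve.** A loess smooth (degree-1 local linear regression,
tricube kernel, span 0.75, `surface = "direct"`) of the binary outcome on
the predicted probability, evaluated on a 100-point even grid over the
observed prediction range, with pointwise Wald bands from the local fit's
standard errors; values are clipped to [0, 1]. Span and degree are the
conventional defaults — no particular smoother parameters are canonical for
calibration plots — and both are exposed as arguments.
`calibration_band_ok()` operationalises "well calibrated up to risk r" as
the smoothed curve staying within a tolerance of the diagonal over a band.

**Classification accuracy.** Sensitivity, false positive rate, negative
predictive value and percent classified low risk, each with a Wilson score
interval. Wilson is used because sensitivities near 100% need an interval
that behaves at the boundary; the interval is additionally clamped to
contain the point estimate to guard against last-ulp rounding. A measure
with a zero denominator is reported `NA` with a `defined = FALSE` marker,
never as zero. McNemar's paired test uses the exact two-sided binomial
tail when the discordant count `b + c` is below 25 and the
continuity-corrected chi-square otherwise; the rule applied is stated in
the result, p-values are capped at 1, and zero discordance returns p = 1
by convention.

**Decision curves.** Net benefit per patient,
`tp/n − (fp/n) · t/(1 − t)`, against treat-all and treat-none over a
default grid of 0.01–0.50 in steps of 0.01 — the clinically debated PUL
thresholds are low, and no smoothing is applied (exactness over
aesthetics). The treat-all curve crosses zero exactly at the cohort
prevalence; a model has utility at a threshold only where its net benefit
exceeds both defaults.

## The synthetic cohort generator

No public PUL dataset exists, so the generator emulates the marginal
structure reported for a large single-centre validation cohort and is the
package's test bed:

- outcome mix 461 : 362 : 238 (failed PUL : IUP : EP) with 46/238 of EP
  labelled persisting PUL;
- first hCG log-normal with median 703 IU/L and log-sd
  `(ln 2312 − ln 210)/(2 z_0.75) ≈ 1.78` so the quartiles match the
  reported 210–2312 IU/L spread;
- class-conditional log-normal hCG ratios (medians: failed 0.50, IUP 2.0,
  EP 1.05; log-sd 0.5), chosen once so the *mixture* median is ≈ 0.94 —
  the class-conditional distributions are unpublished, so these are free
  parameters of the generator, not reproduced facts — truncated to the
  plausible range 0.06–5.65;
- sampling intervals 13% / 71% / 16% across the 24–39 / 40–56 / 57–72 h
  bins, uniform within bin; covariate flag rates (bleeding 68%, prior EP
  7%, IUD 3%, inpatient 8%) as reported.

The generator has two modes. *Descriptive* mode draws outcomes from the
mixture above and is used for marginal-fidelity checks and end-to-end
pipeline runs. *Model-consistent* mode (`simulate_from_model()`) draws
covariates — with a single marginal ratio distribution (median 0.94,
log-sd quartile-matched to the 0.45–1.59 IQR) rather than class-conditional
ones, so predicted risks spread over a realistic range — and then draws
each outcome from the probabilities the supplied model assigns to that
record. Scoring the generating model on such a cohort is perfectly
calibrated *by construction*, which turns calibration and discrimination
code into testable quantities: slope → 1, intercept → 0, and the score AUC
equals the ground-truth-probability AUC. Scoring a *different* model (for
example one with uniformly sharpened logits) must show slope < 1 — the
classic signature of an overfitted or non-transporting model.

Reproducibility is by a single integer seed; all draws happen in a fixed
sequential order inside a locally seeded RNG scope, so a generated cohort
is a pure function of `(params, seed)` and the caller's RNG state is left
untouched.

What passing tests on synthetic cohorts do **not** show: real PUL data
have measurement error and assay-specific hCG behaviour, informative
missingness, within-class heterogeneity (viable vs non-viable IUP),
correlated covariates, and local case mix — none of which the generator
emulates. Results on synthetic cohorts validate the *machinery*, not any
clinical model.

## Problem sizes and test design

Closed-form and oracle checks run on small fixed instances (for example
the 3+3 DeLong placement table, two-point saturated calibration designs).
Stochastic recovery checks use model-consistent cohorts of n = 20,000 over
10 seeds — large enough that the mean calibration slope concentrates
within 1 ± 0.03 and the mean intercept within ± 0.03, while the whole
suite stays fast. The loess-curve recovery criterion is assessed through
the per-seed maximum deviation from the diagonal over predictions in
[0.02, 0.5], averaged over the seeds, consistent with the mean-based slope
and intercept criteria; at n = 20,000 the upper end of that band is
sparsely populated, so an individual seed can graze the band while the
average sits far inside it. Marginal-fidelity checks of the generator use
a single n = 100,000 draw.

## Interface choices

The package is tidyverse-native: every user-facing function takes a data
frame first and returns a tibble (or a tibble-backed result object with
`tidy()` / `glance()` methods), so the whole pipeline composes with the
pipe. The end-to-end entry points are plain functions —
`simulate_pul_cohort()` / `simulate_from_model()`, `pul_validate()`,
`pul_sensitivity()` — rather than a shell executable, since the intended
users work inside R; `write_validation_report()` persists the JSON summary
and plot-ready CSVs that an external reporting step would consume.

Records with gestational trophoblastic disease or lost follow-up are
excluded by `apply_inclusion()` but preserved in the input, so a post-hoc
analysis of how a model scores them remains possible by re-filtering with
the exclusion flags disabled. The interval window is inclusive on both
ends (24 and 72 h are retained). When a record fails several exclusion
criteria at once the log attributes it to the first in the order interval
window, trophoblastic disease, lost to follow-up; published flow-chart
counts that tally overlapping categories separately can therefore differ
slightly from the log, and no attempt is made to force agreement.

## Known limitations

- The bundled model configurations are placeholders; no clinical claim
  attaches to any number computed from them.
- Calibration-curve confidence bands treat the binary outcome as a bounded
  response in a Gaussian local fit; a bootstrap band would be more
  defensible near the extremes.
- Net benefit is reported without confidence intervals.
- The generator draws the two hCG samples for exactly one follow-up visit;
  longitudinal trajectories beyond the persisting-PUL helper are out of
  scope.
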