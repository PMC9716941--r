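# pulvalidate

Tools for externally validating risk-prediction models that triage a
**pregnancy of unknown location (PUL)** — a positive pregnancy test with no
pregnancy visible on transvaginal ultrasound — using two serum hCG
measurements taken 24–72 hours apart. The clinically dangerous outcome is
an **ectopic pregnancy (EP)**; the benign outcomes are an intrauterine
pregnancy (IUP) and a spontaneously resolving ("failed") PUL.

The package is aimed at clinical epidemiologists who need to check whether
a two-hCG triage model transports to their own unit before adopting it:
it provides the model-evaluation machinery, the comparison statistics, and
a seeded synthetic-cohort generator so that every step can be exercised and
tested without patient data.

## The model family

Triage models of this family (M4, M6NP) are polynomial multinomial logistic
regressions on the natural logs of the first hCG level and of the hCG ratio
(second / first). With failed PUL as the reference outcome, each
non-reference outcome *k* ∈ {IUP, EP} has a linear predictor

    eta_k = sum_j beta_kj * f_j(log hCG1, log ratio)

with basis terms drawn from {1, log hCG1, (log hCG1)^2, log ratio,
(log ratio)^2, log hCG1 · log ratio}, and the outcome probabilities are the
softmax (P(failed), P(IUP), P(EP)) ∝ (1, exp eta_IUP, exp eta_EP). A woman
is classified **high risk** when P(EP) ≥ t, conventionally t = 5%.

Coefficients are *configuration, not code*: they are loaded from a JSON
file (`read_model_spec()`), so the published model equations can be
transcribed and validated without touching the package. The bundled
`example_model()` specs are clearly labelled **synthetic placeholders** for
testing the machinery, not the published models.

The validation battery mirrors standard external-validation practice
(TRIPOD):

- **Discrimination** — Mann–Whitney AUC, DeLong variance and 95% CI, and
  DeLong's paired test for two models scored on the same cohort.
- **Calibration** — calibration-in-the-large (intercept of a logistic
  recalibration with slope fixed at 1), calibration slope, and a
  loess-smoothed calibration curve with pointwise confidence band.
- **Classification accuracy** — sensitivity, false positive rate, negative
  predictive value and percent classified low risk at the 2.5/5/10%
  thresholds, with Wilson intervals and McNemar paired comparisons.
- **Clinical utility** — decision-curve analysis: net benefit
  tp/n − (fp/n)·t/(1−t) against the treat-all and treat-none strategies.

## Worked example

Simulate a cohort whose outcomes are drawn from a known model, then
validate that model and a competitor on it:

```r
library(pulvalidate)

m6 <- example_model("m6np")    # synthetic placeholder specs
m4 <- example_model("m4")
cohort <- simulate_from_model(m6, 5000, seed = 2024)
report <- pul_validate(cohort, list(M6NP = m6, M4 = m4))
report
#> PUL external-validation report
#>   cohort: n = 5000, EP prevalence = 11.0% (551 events)
#>   M6NP: AUC 0.784 (0.767-0.802), CITL 0.037, slope 0.939
#>   M4: AUC 0.782 (0.765-0.800), CITL 0.998, slope 0.760
#> Paired DeLong test: AUC 0.784 vs 0.782 (diff 0.002), z = 1.578, p = 0.1147
```

Because the outcomes were generated from the M6NP placeholder, that model
is close to perfectly calibrated (calibration-in-the-large ≈ 0, slope ≈ 1);
the competing spec under-predicts EP on average (CITL ≈ 1.0 log-odds: the
average predicted risk is well below the observed 11% EP rate) and its
slope of 0.76 says its predictions are too extreme. `glance(report)` turns
this into one row per model; `tidy(report)` gives the threshold-by-measure
accuracy table:

```r
dplyr::filter(tidy(report), threshold == 0.05, measure == "sensitivity")
#> # A tibble: 2 × 11
#>   model threshold    tp    fp    tn    fn measure     estimate conf.low conf.high
#>   <chr>     <dbl> <int> <int> <int> <int> <chr>          <dbl>    <dbl>     <dbl>
#> 1 M6NP       0.05   516  2484  1965    35 sensitivity    0.936    0.913     0.954
#> 2 M4         0.05   381  1348  3101   170 sensitivity    0.691    0.652     0.729
```

Calibration curves, ROC points and decision curves are available as plots
(`autoplot()` on the `calibration_curve()` / `decision_curve()` results,
`plot_roc()`) or as CSV exports for external plotting
(`write_validation_report()` writes everything a run produced).
`pul_sensitivity()` repeats a validation with and without the 24–72 h
sampling-interval filter and tabulates the deltas.

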