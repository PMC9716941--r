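Package: pulvalidate
Title: External Validation Toolkit for hCG-Based Pregnancy of Unknown
    Location Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating multinomial logistic triage models that
    predict the outcome of a pregnancy of unknown location (failed PUL,
    intrauterine pregnancy, or ectopic pregnancy) from two serum hCG
    measurements. Provides configurable risk-model evaluation, ROC
    discrimination with DeLong variance and paired tests, logistic
    recalibration (calibration-in-the-large and calibration slope),
    loess-smoothed calibration curves, threshold classification accuracy
    with Wilson intervals and McNemar comparisons, decision-curve
    analysis, and a seeded synthetic cohort generator with known ground
    truth for end-to-end pipeline checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
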