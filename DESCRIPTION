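Package: mmfde
Title: Multi-Metric Fuzzy Distance-Based Ensemble for Clinical Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interpretable fusion of gradient-boosting classifiers for binary
    clinical risk prediction. Base-model probability vectors are mapped into a
    multi-metric distance geometry (Euclidean, Manhattan, cosine, Chebyshev)
    against ideal positive and negative reference vectors, distances are
    converted to fuzzy memberships by exponential decay, and predictions are
    emitted with calibrated confidence levels suitable for risk-stratified
    triage. Includes simplex grid-search weight optimisation, a statistical
    comparison suite (5x2cv paired t-test, McNemar, bootstrap intervals),
    calibration analysis (reliability bins, expected calibration error),
    SHAP-style feature attribution with concordance analysis, and a synthetic
    clinical cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    rpart,
    stats,
    utils,
    xgboost
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
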