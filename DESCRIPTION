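Package: icuconsensus
Title: Consistency Auditing of In-Hospital Mortality Classifiers by
    Repeated-Resampling Decision Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the per-patient stability of intensive-care mortality
    prediction models. Repeats stratified train/test splitting many times,
    trains logistic regression, gradient-boosted trees and adaptive boosting
    alongside a fixed APACHE-style reference probability, binarizes each
    model's test-set predictions at its Youden-index threshold, and fuses the
    accumulated binary votes into consensus groups (true/false
    positive/negative and MIXED) under an agreement threshold. Provides
    Shapley-style additive feature attributions aggregated patient-first then
    population, group-wise feature-distribution comparison (histogram/KDE and
    categorical occurrence shares), and a synthetic ICU cohort generator with
    planted clearly-alive, clearly-dead and ambiguous subgroups, bimodal
    worst-in-24h physiology, and severity-dependent informative missingness,
    so the whole pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    rpart,
    stats,
    tibble,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
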