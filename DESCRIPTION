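Package: afonset
Title: Short-Term Atrial Fibrillation Onset Prediction from Heart Rate
    Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to forecast imminent paroxysmal atrial fibrillation (AF)
    from beat-annotated RR-interval recordings. Implements eligibility rules
    that turn 24-h Holter-style beat series into labelled pre-AF and normal
    sinus rhythm analysis windows, ectopy-aware NN-interval cleaning and
    spline-resampled tachograms, a 45-feature heart-rate-variability battery
    (time-domain, geometric, spectral, Poincare, second-order difference
    plot, phase-rectified signal averaging, and heart-rate fragmentation
    indices), overlapping 5-min segmentation, temporal patient-grouped
    cross-validation of tree-ensemble classifiers with recording-level
    aggregation, a bootstrap metric suite, and exact Shapley-value feature
    attribution. A seeded synthetic RR-cohort generator with the statistical
    structure the analysis assumes makes every stage testable without
    clinical data.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
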