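Package: rplmom
Title: Gestational-Age-Specific MoM Normalization and Cross-Validated
    Biomarker Discrimination for Recurrent Pregnancy Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing first-trimester maternal serum biomarkers
    (free beta-hCG, PAPP-A, PlGF) in recurrent pregnancy loss case-control
    studies. Implements gestational-age-specific daily multiple-of-median
    (dMoM) normalization from published log10 daily-median reference
    equations, cohort validation and per-analyte reference-window filtering,
    two-group comparisons, and a repeated stratified cross-validation
    protocol for logistic-regression biomarker panels reporting averaged ROC
    curves, AUC, sensitivity at fixed false-positive rates, and likelihood
    ratios. A synthetic cohort generator with binormal AUC calibration makes
    the whole pipeline testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
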