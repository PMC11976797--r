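Package: stk11eval
Title: Assessment of Kinase-Activity Predictors for STK11 Variants
Version: 1.0.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking computational variant-effect predictors
    against a cell-based luciferase reporter assay of STK11 (LKB1) kinase
    activity. Normalizes raw per-replicate luminescence to relative-wildtype
    (R-WT) activity, derives binary loss-of-function labels, evaluates
    predictors with Pearson correlation, Kendall tau-b and ROC AUC under
    stratified bootstrap resampling, derives a replicate-resampling
    Experimental-Max upper bound on achievable performance, profiles
    difficult-to-predict variants via per-variant FPR/FNR, and performs
    ACMG/AMP point-based clinical variant classification combining
    functional, computational, population-frequency and co-located-variant
    evidence. Includes a synthetic assay/predictor generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
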