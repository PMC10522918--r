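Package: prognoscore
Title: Multi-Cohort Discovery and Application of Prognostic Gene-Expression Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for weighted-sum prognostic gene-expression
    signatures from multi-cohort survival studies. Screens genes by
    censoring-aware time-dependent ROC dichotomization (constrained optimal
    cutoff) and dual univariate/multivariate Cox regressions replicated across
    cohorts, pools per-cohort coefficients by fixed- or random-effects
    meta-analysis according to Cochran's Q and Higgins' I-squared, exhaustively
    enumerates and evaluates weighted-sum scores against hazard-ratio and
    discrimination thresholds, and applies the selected score: median
    normalization into low/intermediate/high categories, integration with AJCC
    TNM staging into combined risk groups, tertile-based benchmarking of
    external published signatures, and drug-sensitivity correlation on
    cell-line panels. Includes a multi-cohort synthetic-data generator with
    planted prognostic genes and between-cohort effect heterogeneity so every
    stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
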