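Package: lumityper
Title: Molecular Subtyping, Recurrence Risk and Immune Scoring for
    HR+/HER2- Early Breast Cancer Expression Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing targeted RNA-seq panels in hormone
    receptor-positive, HER2-negative early-stage breast cancer. Implements
    sample quality control and counts-per-million normalisation for a
    72-gene panel (50 subtype, 17 immune, 5 housekeeping genes),
    nearest-centroid intrinsic subtyping with a proliferation-weighted
    risk-of-recurrence score, a 21-gene recurrence score, a 17-gene immune
    score with ROC-derived grouping, St. Gallen and modified
    immunohistochemistry surrogate subtype rules including basal-like
    identification, and downstream concordance (Cohen's kappa) and
    survival (Kaplan-Meier, log-rank, Cox) statistics. A synthetic-cohort
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
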