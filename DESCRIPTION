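Package: iciscore
Title: Immune-Evasion Modelling and ICI Response Scoring for Urothelial Carcinoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores bulk expression cohorts of urothelial carcinoma with
    single-sample gene-set enrichment (ssGSEA) for luminal, basal,
    cytotoxicity and immunosuppressive-macrophage (Macro-C3) signatures;
    places samples on a log(basal/luminal) subtype axis; fits an
    immune-evasion model as the intersection of two regression lines
    (z-scored cytotoxicity and Macro-C3 scores against the subtype axis)
    whose crossing defines a cohort threshold; and emits a piecewise
    immune-checkpoint-inhibitor (ICI) response score that equals the
    Macro-C3 score below the threshold and the cohort-minimum Macro-C3
    score above it. Includes ROC/AUC and quartile evaluation utilities,
    single-cell quality-control and high-confidence differential-expression
    rules, a permutation ligand-receptor interaction screen, and synthetic
    bulk and single-cell data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
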