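Package: drqual
Title: Quality-Aware EC50 Modeling from Raw Dose-Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw dose-response measurements into EC50/IC50 targets with
    per-molecule fit-quality metrics, via two-parameter Hill-equation
    regression or a discretized Bayesian posterior, and trains quality-aware
    regression models: random forests with parametric bootstrap, weighted
    splits, (variable) output smearing, and per-sample-cost weighted support
    vector regression. Models are compared by predicting held-out raw
    dose-response outcomes rather than possibly unreliable test-set EC50s,
    with bootstrap uncertainty and Wilcoxon signed-rank comparisons. Includes
    a synthetic-data generator emulating uniform-quality (PubChem-like) and
    heteroscedastic (BASF-like) assay regimes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    rpart
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
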