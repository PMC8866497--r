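Package: textconfound
Title: Uncovering Text-Derived Confounders for Observational Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Uncovers interpretable potential confounders from clinical free
    text and evaluates them with propensity-adjusted time-to-event analysis.
    Clinical notes are featurized into interpretable term-frequency (TF-IDF)
    covariates, covariates predictive of both treatment assignment and
    survival are selected by intersecting the supports of an L1-penalized
    logistic treatment model and an L1-penalized Cox outcome model, and the
    treatment hazard ratio is estimated under nearest-neighbour propensity
    matching, stabilized inverse-probability-of-treatment weighting, and a
    doubly robust weighted multivariate Cox model. Ships a synthetic
    EMR-cohort simulator with planted text-borne confounding so the whole
    workflow is testable end to end without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    randomForest,
    xgboost,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
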