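Package: connpred
Title: Connectome-Based Prediction of Age and Cognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Connectome-based predictive modelling of age and cognitive
    scores from resting-state functional connectivity. Provides Fisher-z
    connectome construction and upper-triangle vectorization, partial
    least squares regression (SIMPLS) inside a repeated k-fold
    cross-validation framework with permutation significance, weight-map
    interpretation at the connection, node and network level, stability
    diagnostics (bootstrap weight maps, inter-correlation of fold models,
    network-restricted models, a CPM cross-check), per-edge bootstrap
    mediation of the age-cognition association with FDR control,
    frozen-model transfer to external cohorts via dot product, and a
    synthetic-cohort generator with network-structured edge effects so the
    whole pipeline can be exercised without access to any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
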