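Package: fncpredict
Title: Static and Dynamic Functional Network Connectivity Prediction of
    Treatment Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting clinical outcome changes from
    intrinsic connectivity network (ICN) time courses. Implements network
    time-course post-processing (polynomial detrending, motion regression,
    despiking, band-pass filtering), static functional network connectivity
    (FNC) features, sliding-window dynamic FNC with a graphical-lasso
    per-window estimator, meta-state global-dynamism summaries via fuzzy
    k-means, and partial least squares regression prediction under repeated
    ten-fold cross-validation with permutation nulls, confound regression,
    static-versus-combined model comparison, and domain-level predictive
    weight anatomy. A synthetic two-session cohort generator with plantable
    connectivity and dynamism effects makes every stage testable without
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
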