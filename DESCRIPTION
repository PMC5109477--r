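Package: ctcdyn
Title: Stiffness, Correlation and Time-Delayed Causality Analysis of
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("ctcdyn", "developers", email = "ctcdyn@example.org",
           role = c("aut", "cre"))
Description: Fluctuation-based analysis of molecular dynamics trajectories:
    pairwise spring constants (Gaussian-network stiffness) from residue
    fluctuation covariances, dynamic cross-correlation maps, residue-pair
    distance distributions, time-delayed auto- and cross-correlations with
    1/e decay times, and conditional time-delayed correlation (CTC)
    causality scans that identify driver/follower residue pairs. Includes
    coupled Ornstein-Uhlenbeck and Gaussian-ensemble generators with
    analytic lagged-covariance oracles so every estimator is testable
    against known ground truth, plus a command-line interface that ties
    the pipeline together from trajectory (or synthetic) input to CSV,
    JSON, GraphML and figure output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
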