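Package: dynfc
Title: Dynamic Functional-Connectivity States and Time-Varying Network Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dynamic functional connectivity (dFC) of
    resting-state network time courses: post-ICA time-course cleaning
    (polynomial detrending, despiking, nuisance regression, zero-phase
    low-pass filtering), tapered sliding-window covariance estimation with
    graphical-LASSO regularization and Fisher r-to-z transformation,
    k-means decomposition (Manhattan distance, median centroids) of windowed
    connectivity into recurring states with fractional-window, dwell-time
    and transition metrics, binarized graph-theory metrics (global/local
    efficiency, clustering, path length, small-worldness) with AUC over a
    sparsity grid and their variance over time, and a group-comparison /
    partial-correlation statistics layer. Includes a hidden-Markov
    covariance-switching cohort simulator with ground-truth labels so the
    whole pipeline is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    withr
Config/testthat/edition: 3
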