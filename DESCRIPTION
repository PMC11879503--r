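Package: psynet
Title: Regularized Partial Correlation Networks, Stability, Comparison and
    Bayesian Networks for Questionnaire Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Network-psychometric analysis of questionnaire subscale scores:
    Spearman-based Gaussian graphical models estimated by an EBIC-regularized
    graphical lasso, node and bridge centrality indices with predictability,
    nonparametric bootstrap accuracy and case-dropping stability (CS
    coefficients), permutation-based network comparison tests between groups,
    and score-based Bayesian network (DAG) structure learning with bootstrap
    arc strengths and consensus-network thresholding. Includes a synthetic
    questionnaire-data generator with known ground-truth partial-correlation
    or DAG structure for parameter-recovery testing, and a pipeline driver
    that runs the full analysis from a single configuration.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    e1071,
    withr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
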