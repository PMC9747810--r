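Package: mcse
Title: Minimum Convergence Sample Estimation for Fully Connected Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the minimum number of labeled samples a fully
    connected neural-network classifier needs before it begins to
    generalize, using only unlabeled data. A matched autoencoder is trained
    across a doubling schedule of sample sizes with bootstrapped
    replicates; the inflection point (argmax of the second derivative) of
    the natural-spline-smoothed reconstruction-loss curve gives the
    minimum convergence sample estimate (MCSE). Includes a
    hypercube-cluster synthetic data generator with controllable label
    noise, pre/post-MCSE correlation reports (R-squared, Kendall's tau,
    Spearman's rho), and linear extrapolation of the sample size required
    for a target test AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    patchwork,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
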