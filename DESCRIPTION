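Package: firtest
Title: Significance Testing of Two-Way Feature Interactions with Stratified Gradient Boosting
Version: 0.1.0
Authors@R:
    person("Firtest", "Developers", email = "maintainer@firtest.dev", role = c("aut", "cre"))
Description: Detects and tests two-way feature interactions in tabular
    regression data using the feature interaction ratio (FIR): the mean
    cross-validated RMSE of four gradient-boosted machines fitted within
    median-defined strata of a candidate feature pair, divided by the RMSE of
    a single machine fitted without the pair. Significance is declared against
    the empirical FIR distribution over all feature pairs using the Tukey
    boxplot fence Q1 - 1.5*IQR. Includes a multivariate-normal synthetic data
    generator with subgroup interaction injection, a multiple-regression
    product-term baseline, and a simulation harness estimating type-I error
    and power with binomial confidence intervals. The boosted-tree engine is a
    deterministic exact-greedy implementation in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
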