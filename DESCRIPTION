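Package: triglmm
Title: Simultaneous Hierarchical Models for Correlated Binary Survey Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits three-level random-intercept logistic models to binary
    outcomes collected in cluster/household surveys, both one outcome at a
    time and simultaneously.  The simultaneous model places a trivariate
    normal random intercept at the cluster level and another at the
    household level, with cross-outcome covariance within each level and
    independence across levels; a six-degree-of-freedom likelihood-ratio
    test of the cross-outcome covariances decides whether the joint model
    is needed.  Marginal likelihoods are evaluated by nested adaptive
    Gauss-Hermite quadrature.  Includes a seeded generator for synthetic
    hierarchical survey data, latent-scale intraclass correlations for
    logistic models, outcome-pattern tabulation, and side-by-side
    comparison of separate and joint fits.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    rlang,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
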