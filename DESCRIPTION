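Package: bmsdesign
Title: Optimal Experimental Design for Bayesian Model Selection of Brain
    Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Ranks candidate experimental designs by how well they
    discriminate competing generative models of neuroimaging time series.
    Implements the Laplace-Chernoff risk, an information-theoretic proxy
    for the Bayesian model selection error rate built from Jensen-Shannon
    divergences between Laplace approximations of each model's prior
    predictive density, together with exact low-dimensional oracles,
    the general-linear-model special case and its classical C-optimality
    limit, a bilinear dynamic causal model (DCM) forward simulator with
    balloon hemodynamics, a variational-Laplace model inverter, and
    Monte-Carlo machinery for validating the error-rate bounds on
    synthetic BOLD data.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
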