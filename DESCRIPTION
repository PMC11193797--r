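Package: mlalaam
Title: Multilevel Autologistic Actor-Attribute Models for Household Wealth Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multilevel (household-region) social networks from
    household membership records, derives asset-based wealth indices,
    quintile-Gini regional inequality scores and binary change outcomes,
    and fits multilevel autologistic actor-attribute models (ALAAM) with
    geographically defined network configurations. Includes a calibrated
    synthetic population generator, a compiled Gibbs sampler, Robbins-Monro
    MCMC maximum-likelihood estimation, exact small-network likelihoods,
    goodness-of-fit t-ratios, baseline logistic regressions with average
    marginal effects, and a step-wise model-ladder and pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
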