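Package: flywaytrends
Title: Detection-Corrected Population Trends for Migratory Shorebirds and
    Their Phylogenetic Comparative Drivers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage Bayesian inference for flyway-scale population trends of
    migratory shorebird taxa from replicated non-breeding-season counts.
    Stage one fits hierarchical binomial-Poisson N-mixture models by MCMC,
    estimating detection-corrected abundance and log-linear trends at the
    level of non-breeding nodes or the whole flyway, with posterior
    predictive checking and pairwise node-trend odds ratios. Stage two
    explains variation in flyway trends across taxa with a Bayesian linear
    regression carrying Brownian-motion phylogenetic residual covariance
    integrated over a set of ultrametric trees, using indicator-variable
    Bayesian variable selection and a two-stage refit. A synthetic-data
    generator with known ground truth reproduces the statistical structure of
    restricted monitoring data so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    lme4,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
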