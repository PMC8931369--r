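Package: allogrades
Title: Phylogenetic Detection of Shifts in Allometric Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for inferring changes in allometric scaling rules on a
    time-calibrated phylogeny. Implements phylogenetic generalized least
    squares with Pagel's lambda, reversible-jump MCMC over multi-regime
    Ornstein-Uhlenbeck regressions to locate shifts in slope and intercept
    without specifying them a priori, a model-selection cascade that merges
    candidate allometric grades and detects convergent regimes, fold-change
    and relative-measure statistics, Brownian-motion ancestral state
    reconstruction, and multi-rate comparisons of residual evolution.
    Includes a synthetic-data generator with planted regime shifts for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    Rcpp,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    coda,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
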