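Package: horizontask
Title: Directed and Random Exploration Analysis for Horizon-Task Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing explore-exploit behaviour in the Horizon
    Task, a two-armed Gaussian bandit with forced-choice trials that
    dissociates directed exploration (information seeking) from random
    exploration (decision noise). Implements Kalman-filter reward learning
    in learning-rate space, a logistic choice rule with an information
    bonus and spatial bias, hierarchical Bayesian estimation of the
    thirteen subject-level parameters per stimulation condition via an
    adaptive Metropolis-within-Gibbs sampler, posterior contrasts between
    conditions, model-free exploration statistics with repeated-measures
    ANOVA, and a synthetic-study generator with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    purrr,
    stats,
    utils,
    coda,
    jsonlite,
    yaml,
    ggplot2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
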