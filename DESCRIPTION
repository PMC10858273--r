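Package: triadug
Title: Simulation and Bayesian Analysis of Triadic Ultimatum Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing repeated
    dyadic and triadic ultimatum-game experiments in which two proposers
    compete to have their food offers accepted by a single responder.
    Provides the counterbalanced 16-session experimental schedule, an
    agent-based game engine with a configurable strategy zoo, descriptive
    statistics, a hierarchical Bayesian model suite (Beta regression with
    modelled precision for total proportional offers, Bernoulli mixed
    models for offer escalation, and a monotonic-ordinal outbidding model
    fitted by MCMC), a weighted-resampling baseline null for outbidding
    probabilities, and a simulation-based power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
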