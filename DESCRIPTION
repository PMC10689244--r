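Package: metabandit
Title: Meta-Reinforcement Learning Analysis for Baited Reversal Bandit Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for probabilistic reversal
    learning with reward baiting. Provides the task environment (baited
    two-port bandit with uncued block reversals and a performance-gated
    transition rule), a session-batched recurrent actor-critic agent
    trained with advantage actor-critic (A2C) and truncated
    backpropagation through time, behavioral policy models (choice- and
    reward-history logistic kernels, a forgetting Q-learning model with
    cross-validated regularization), trial-difference population decoders
    of value-related signals with chance-floor procedures, coding-axis
    geometry across longitudinal sessions, and a synthetic-data generator
    that supplies ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
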