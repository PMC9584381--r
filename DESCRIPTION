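Package: pitfit
Title: Rescorla-Wagner Modelling of Pavlovian-Instrumental Transfer Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of the four-stage
    Pavlovian-instrumental transfer (PIT) paradigm: probabilistic instrumental
    training with a learning criterion, deterministic Pavlovian conditioning,
    transfer under extinction, and a forced-choice cue test. Provides a
    nine-model space of modified Rescorla-Wagner learning models (separate
    reward/punishment learning rates and sensitivities, response bias,
    additive Pavlovian factors, value decay and per-stimulus generalization
    noise), trial-by-trial softmax choice likelihoods, maximum a posteriori /
    expectation-maximization random-effects fitting with Laplace-approximated
    log-model evidence, a synthetic-cohort generator with known ground truth,
    and the standard model-free behavioral measures (trials to criterion,
    win-stay/lose-switch, per-cue keypress means, collection probabilities,
    PIT regression slopes, forced-choice accuracy).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    dplyr,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
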