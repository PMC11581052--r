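Package: aifbandit
Title: Active Inference Modelling of Three-Armed Bandit Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, model inversion and group-level analysis of
    three-armed bandit choice behaviour. Implements an active inference
    agent that learns action-outcome contingencies as Dirichlet
    concentration parameters with separate win/loss learning rates, a
    forgetting rate producing recency bias, a pessimism prior over
    untried actions, and outcome-dependent decision noise; together with
    Rescorla-Wagner comparison models, MAP estimation with a Laplace
    approximation to the model evidence, random-effects Bayesian model
    selection (protected exceedance probabilities), model-free behavioural
    metrics (win-stay/lose-shift, iterative Grubbs screening, reaction-time
    coupling), synthetic cohort generation with planted group effects, and
    frequentist and parametric-empirical-Bayes group inference.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    emmeans,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
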