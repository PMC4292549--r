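Package: gatingmcmc
Title: Bayesian Markov-Chain Inference of Ion-Channel Gating Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits continuous-time Markov models with aggregated conductance
    classes (open, sub-conductance, closed) to single-channel current
    recordings by random-walk Metropolis-Hastings sampling of the
    transition-rate matrix under an exponential prior. Provides threshold
    idealization of sampled current traces, run-compressed forward
    likelihoods for aggregated event sequences, Colquhoun-Hawkes dwell-time
    densities, stationary-distribution analysis with detailed-balance
    cross-checks, an exact stochastic (Gillespie) simulator for generating
    synthetic recordings, and a command-line interface tying the pieces
    into simulate / idealize / fit / dwell / stationary workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
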