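Package: bibswarm
Title: Bayesian and Inverse Bayesian Inference for Collective Animal Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A hypothesis-update engine coupling Bayesian belief revision over a
    finite hypothesis set with inverse Bayesian replacement of likelihoods by
    windowed empirical frequencies, together with the experiments built on it:
    tracking a sinusoidally drifting symbol source, a trajectory-analysis
    pipeline for multi-individual 2-D tracking data (polarization order
    parameter, discretized relative-density streams, future-frequency
    benchmarks), an agent-based swarm simulator whose agents steer by velocity
    alignment and an inferred local-density preference, and seeded synthetic
    generators for regime-switching symbol streams and phase-alternating
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
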