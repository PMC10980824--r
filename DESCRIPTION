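Package: mserd
Title: Multiscale Envelope Resting-State Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale analysis of resting-state neural dynamics from
    amplitude-envelope time series. Fast sub-second network dynamics are
    modelled with a Gaussian-observation hidden Markov model fitted on
    standardized, concatenated, PCA-reduced power envelopes (Viterbi
    decoding; fractional occupancy, mean lifetime, interval length and
    occurrence counts per state, subject and session). Slow supra-second
    dynamics are captured by amplitude-envelope correlation connectomes
    with network-based permutation statistics (suprathreshold connected
    components, family-wise error control). The two scales are linked
    through state networks (nodes where a state's power map exceeds a
    fraction of its maximum) and their mean connectivity strength, and
    related to finger-tapping motor performance indices (global
    performance index, best motor performance, learning index, offline
    changes). A synthetic generator with known Markov-switching ground
    truth makes the whole pipeline testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    igraph,
    car,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
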