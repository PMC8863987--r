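Package: mph2mm
Title: Multi-Parameter Photon-by-Photon Hidden Markov Modeling for
    Single-Molecule FRET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Photon-by-photon hidden Markov modeling of single-molecule
    FRET data with multiple detection streams (mpH2MM). Infers the number
    of interconverting states, their raw FRET efficiency (E_raw) and
    stoichiometry (S_raw) signatures, and transition rate constants
    directly from photon arrival times, propagating transitions across
    inter-photon gaps via exact matrix powers. Includes integrated
    complete likelihood (ICL) and modified BIC model selection, Viterbi
    dwell-time analysis, burst search and selection (sliding window and
    dual-channel), burst variance analysis, photon-HDF5 and plain-text
    photon I/O for nsALEX and microsecond-ALEX experiments, and a
    continuous-time Markov photon simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    pracma,
    optparse
Config/testthat/edition: 3
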