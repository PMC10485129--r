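Package: fatepattern
Title: Cell Fate Patterning from Coupled Transcription-Factor Switches on Cell Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-transcription-factor cell fate switch coupled by
    tissue-wide signaling on irregular cell contact graphs. Binding
    probabilities of the antagonistic factors are derived from Boltzmann
    statistics of promoter occupancy; the resulting ODE system is integrated
    to steady state under nearest-neighbor-averaged or distance-based
    (dispersion) signaling kernels. Provides the analytic stability interval
    guaranteeing heterogeneous (two cell type) patterns, cell type proportion
    sweeps and ratio bisection, and graph-distance pair correlation functions
    for quantifying checkerboard versus engulfing patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
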