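Package: stochcirc
Title: Stochastic Ensemble Modeling of Gene Regulatory Circuits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates ensembles of randomly parameterized kinetic models of a
    gene regulatory circuit from its topology alone, simulates them as
    stochastic differential equations (Euler-Maruyama, shifted-Hill
    regulation) under single-initial-condition, constant-noise
    multiple-initial-condition (MIC) and simulated-annealing (SA) sampling
    schemes, and quantifies multistability, basins of attraction versus state
    stability, noise-induced state merging, parametric-variation effects, and
    circuit noise robustness through Bhattacharyya-distance metrics.
    One-dimensional double-well potential benchmarks for the sampling schemes
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
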