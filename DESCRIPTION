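Package: fracAD
Title: Fractional-Order Modelling of Alzheimer's Disease Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for a Caputo fractional-order compartmental model of
    Alzheimer's disease coupling functional neurons, infected neurons,
    amyloid-beta, tau protein and microglia. Provides a Grunwald-Letnikov
    memory-convolution integrator with a Mittag-Leffler oracle, equilibrium
    and next-generation-matrix reproduction-number analysis, eigenvalue
    stability classification with stabilizing gains, logarithmic parameter
    sensitivity, a fractional physics-informed neural network (with
    integer-order and data-only baselines) benchmarked under observation
    noise, and therapeutic-control scenario comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
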