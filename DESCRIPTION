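Package: spikeverify
Title: Verification and Substantiation of Spiking Network Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for verifying numerical implementations of spiking neural
    network simulations and quantifying the agreement between two executable
    models of the same mathematical model. Implements the Izhikevich
    polychronization network with interchangeable integration schemes (grid
    forward Euler, sub-stepped symplectic Euler with precise threshold
    detection, and an adaptive Runge-Kutta-Fehlberg reference), in IEEE double
    precision or in emulated 32-bit signed fixed-point (Q-format) arithmetic
    with wrap-around overflow as used on neuromorphic hardware. Provides a
    frozen-state replay protocol for comparing network states, and spike-train
    statistics (firing rate, local coefficient of variation, pairwise
    correlation on binned trains) summarized by Cohen's d effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
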