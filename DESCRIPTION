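Package: oanet
Title: Delayed Mean-Field Kuramoto Models of Large-Scale Brain Synchrony
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of a parsimonious large-scale brain model
    in which every cortical region is an infinite ensemble of Kuramoto
    oscillators reduced, via the Ott-Antonsen ansatz, to one complex order
    parameter per region. Regions interact through a weighted connectome with
    distance-dependent conduction delays, integrated with a time-delayed Euler
    scheme. The package bundles a finite-size microscopic Kuramoto simulator
    used as a brute-force oracle for the reduction, alpha-band amplitude
    envelope functional connectivity (static and time-resolved with
    Kolmogorov-Smirnov comparison of recurrence distributions), synchrony and
    metastability observables, a constrained multi-run fitness function, and
    stochastic optimizers (particle swarm and self-adaptive differential
    evolution) for homogeneous and homotopically-tied heterogeneous coupling
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
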