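Package: dictyoswarm
Title: Coarse-Grained Simulation and Criticality Diagnostics of
    Dictyostelium Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of starvation-induced Dictyostelium
    discoideum aggregation by pulsed cAMP relay (rear-biased secretion,
    threshold-gated chemotaxis, refractory dynamics, mutant variants),
    together with the statistics used to diagnose critical-like collective
    behavior: density pair correlation, nonconnected and connected
    directional correlations, correlation length, susceptibility,
    finite-size scaling, curve collapse, and a Fourier-space Shannon
    spatial-information measure of images of cells.  Includes a
    zero-dimensional FitzHugh-Nagumo excitable cAMP unit, centroid
    detection and nearest-neighbor track linking, and seed-deterministic
    synthetic-data generators (point processes, correlated direction
    fields, rendered cell images) so every analysis is exercisable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
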