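Package: poretis
Title: Replica-Exchange Transition Interface Sampling for Membrane Pore
    Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-state infinite-swap replica-exchange transition interface
    sampling (RETIS) for rare events, specialised for pore formation and lipid
    translocation in lipid bilayers.  Provides the membrane collective
    variables (chain coordinate, pore expansion, local leaflet proximity,
    translocation distances and leaflet count imbalance) with self-consistent
    cylinder localisation under periodic boundaries, a path-ensemble engine
    with shooting, wire-fencing, point-exchange and infinite-swap moves over a
    pluggable dynamics backend, an iterative initialisation protocol that
    grows reactive paths from equilibrium configurations, and downstream
    kinetics analyses: crossing-probability matching, initial flux and rate
    constants, free-energy and committor projections, effective-positive-flux
    transmission coefficients, block-averaged errors and translocation
    classification.  A two-dimensional Langevin double-well engine and a
    parametric pseudo-bilayer frame generator allow the full stack to be
    exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
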