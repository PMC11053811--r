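Package: demicellr
Title: Reactive Coarse-Grained Simulation of Depolymerizable Copolymer Micelles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bead-spring Langevin dynamics for amphiphilic linear and miktoarm
    star copolymers with trigger-activated head-to-tail depolymerization of the
    hydrophobic blocks. Builds molecule templates and random initial
    configurations, integrates a Kremer-Grest style force field (truncated
    Lennard-Jones pair potential plus FENE bonds) under periodic boundaries,
    applies stochastic end-cap scission and propagation reactions, and provides
    the full analysis stack: micelle identification by the Stillinger contact
    criterion, aggregation-number distributions, gyration and shape anisotropy
    metrics, cargo encapsulation and loading capacity, tracer autocorrelation,
    mean squared displacement, cargo release curves and Korsmeyer-Peppas
    release-kinetics fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
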