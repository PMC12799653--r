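Package: stnnfr
Title: Exact k-Nearest-Neighbour Search by Stochastic Fixed-Radius Queries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact k-nearest-neighbour search that bounds the training set in a
    p-dimensional hypersphere, assumes a spherical uniform dispersion of training
    points, and solves for a per-query search radius whose hypersphere is expected
    to contain a target fraction tau of the training mass. Neighbours are then
    retrieved with fixed-radius KD-tree queries under an escalating tau schedule,
    returning results identical to brute-force search at a fraction of the cost.
    Includes closed-form and numerically solved hypersphere-cap and intersection
    volumes, a brute-force reference search, seeded synthetic-data generators, a
    benchmark harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
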