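Package: latmix
Title: Miscibility Limits of Chaperone-Client Lattice Mixtures
Version: 0.1.0
Authors@R:
    person("Morgan", "Hartley", email = "mhartley@example.org",
           role = c("aut", "cre"))
Description: Patchy-particle lattice model of a mixture of aggregation-prone
    client proteins and passive molecular chaperones, together with the
    machinery needed to locate the miscibility limit (critical surface) of the
    mixture: flat-histogram biased grand-canonical Monte Carlo sampling with a
    compiled inner loop, histogram reweighting across thermodynamic fields,
    and Wilding-Bruce mixed-field finite-size scaling against the universal
    three-dimensional Ising ordering distribution. Includes critical-ensemble
    observables (chaperone dimerization probability, miscibility-limit
    response functions and the chaperone design window), a brute-force
    truncated grand-canonical enumeration oracle for validation on tiny
    lattices, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
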