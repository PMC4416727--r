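Package: osotua
Title: Need-Based Risk-Pooling Networks under Correlated Disasters
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of a need-based livestock-transfer
    insurance scheme (the Maasai 'Osotua' gift-giving system) on spatially
    embedded social networks subjected to repeated disasters. Provides a
    correlated space-time disaster generator (Gaussian cluster sampling on a
    location-by-year lattice), Watts-Strogatz ring-rewired and power-law
    network constructors, the 50-year herd-survival dynamics with need-based
    requests and all-or-nothing gifts, and analysis of the disaster-activated
    gift-flow networks (path length, degree, clustering, simple-cycle counts,
    degree-preserving randomized null models). Includes a sweep driver for
    scenario x correlation-level x rewiring experiments with seeded
    reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
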