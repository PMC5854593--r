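Package: netctrl
Title: Structural Controllability and Optimal Cost Control of Directed Networks with Local Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for controlling directed complex networks when only local
    topological information is available. Implements a distributed local-game
    matching (LM) protocol that identifies driver nodes by exchanging
    parent/child requests between neighbouring nodes, with an exact
    maximum-matching oracle for comparison; a min-max allocator (MLCP) that
    distributes extra control inputs over control paths to minimize the longest
    control path; and a finite-horizon minimum-energy control module with the
    controllability Gramian, expected control cost, its analytic gradient, and
    an orthonormal-constraint projected gradient method (OPGM) for optimizing
    the input matrix. Includes reproducible generators for the synthetic
    topologies used in validation (Erdos-Renyi, directed preferential
    attachment, configuration models with Chi-squared/Weibull/Gamma degree
    laws, and elementary stems, circles and dilations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    xml2
Suggests:
    deSolve,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
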