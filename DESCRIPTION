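Package: pairsis
Title: Pair-Approximation SIS Dynamics and the Evolution of Global Versus
    Local Viral Spread on Heterogeneous Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the within-host competition between cell-free (global) and
    cell-to-cell (local) viral transmission on a two-dimensional lattice in
    which only some sites carry target cells. Provides generators and summary
    statistics for heterogeneous target-cell lattices with prescribed singlet
    and pair densities, the pair-approximation SIS ordinary differential
    equations for one and two virus strains, closed-form and next-generation-
    matrix basic reproduction numbers, endemic-threshold analysis, an
    adaptive-dynamics layer (invasion fitness, pairwise invasibility plots,
    local ESS detection), and a stochastic lattice simulator for single-strain
    persistence and multi-strain evolutionary dynamics with mutation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
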