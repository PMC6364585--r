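Package: scemsort
Title: Subcellular Element Simulation of Cell Doublets and Sorting in
    Multicellular Aggregates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-dimensional, force-based simulator of cell doublets and
    small multicellular aggregates built on the subcellular element method.
    Cells are clouds of elements interacting through short-range Morse
    potentials and evolved by overdamped Langevin dynamics; each cell carries
    a contractile cortex represented as a triangulated tension network whose
    edge tension is reduced at cell-cell interfaces (differential interfacial
    tension) and whose inter-cell adhesion is density-normalised. The package
    measures doublet interface proportions against the analytic linear force
    balance model, grows aggregates by cell growth and division, and
    quantifies inside-out sorting with radius, neighbour and surface measures
    standardised against a label-permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    RANN
Config/testthat/edition: 3
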