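Package: srev
Title: Self-Returning Excluded-Volume Chromatin Chain Simulation and Packing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates coarse-grained chromatin conformations with the
    self-returning excluded-volume (SR-EV) model: a self-returning random
    walk with heavy-tailed forward jumps is expanded into a linear
    nucleosome bead chain and relaxed against a soft repulsive potential
    until all excluded-volume overlaps are resolved.  Includes genomic
    (base-pair) annotation of the chain, ensemble polymer statistics
    (end-to-end scaling, Flory exponents, contact probability), spatial
    density statistics (coordination numbers, chromatin volume
    concentration, pair correlation and its cumulative integral, packing
    parameter D), density-image rendering, and identification of packing
    domains from rendered images via mass-scaling stopping criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
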