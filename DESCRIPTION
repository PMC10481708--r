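Package: fcnc
Title: Persistent Homology of Brain Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Topological analysis of resting-state functional connectivity.
    Builds Vietoris-Rips filtrations from correlation-derived distance
    matrices over brain regions, computes 0- and 1-dimensional persistence
    barcodes with representative cycles by boundary-matrix reduction over
    GF(2), derives functional connectivity neural circuit (FCNC) features
    (per-region cycle involvement and cycle-length counts at chosen
    thresholds), and compares two groups of scans with Mann-Whitney U
    tests, two-sample Kolmogorov-Smirnov tests on Betti curves, and
    Benjamini-Hochberg false-discovery-rate correction. Includes a
    synthetic-data generator that plants correlation ring structures with
    known 1-dimensional homology for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
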