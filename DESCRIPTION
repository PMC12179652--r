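Package: boletax
Title: Tandem-Repeat Detection in ITS, GCPSR Species Delimitation and
    Spore Morphometrics for Bolete Taxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the three computational procedures behind a
    multi-locus re-assessment of bolete (Boletaceae) species: detection and
    characterisation of microsatellite and minisatellite tandem-repeat
    insertions within the nuclear ribosomal ITS region using a wraparound
    dynamic-programming aligner with TRF-style 2-7-7 and 2-3-5 weight
    settings and a two-pass ITS2 protocol; rule-based Genealogical
    Concordance Phylogenetic Species Recognition (GCPSR) over per-locus
    genealogies annotated with bootstrap and posterior-probability supports,
    classifying lineages as phylogenetic or putative species; and spore and
    pileipellis morphometrics using the (minimum of averages) mean +/- sd
    (maximum of averages) convention, length/width quotients, ellipsoid
    spore volumes and bivariate-Gaussian isoprobability ellipses. Seeded
    generators produce synthetic gene-tree sets, ITS sequences with planted
    repeat insertions, and grouped bivariate spore measurements so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    phangorn
Config/testthat/edition: 3
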