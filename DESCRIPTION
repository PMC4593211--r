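Package: mirstack
Title: Read-Stack Driven miRNA Discovery, Triage and Comparative Profiling for
    Insect Small-RNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a small-RNA analysis pipeline for
    stage-structured insect libraries: length filtering and read collapsing,
    stringent seed-and-extend genome mapping, excision and folding of candidate
    hairpin precursors with a dinucleotide-shuffle stability test, homology
    triage of candidates against a miRBase-style reference (known, iso and
    novel classes), a presence-based decision tree for novel miRNA calls,
    TMM-normalized exact-test differential expression with hierarchical
    expression profiling, tandem genomic cluster detection and cross-species
    arrangement comparison, and a simplified seed-anchored 3'UTR target
    scanner. A synthetic-data module generates genomes, annotations and
    stage-structured libraries with known truth so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    edgeR,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
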