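Package: mircurate
Type: Package
Title: Biogenesis-Guided Curation of Mammalian miRNAs from Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating candidate microRNA precursors from collapsed
    small RNA sequencing reads. Reads are aligned to flank-extended precursor
    hairpins at bounded edit distance, the bimodal ~22-nt read signature of
    Drosha/Dicer processing is detected, the hairpin foldback and 2-nt 3'
    overhangs are verified on a predicted secondary structure, and an ordered
    accept/reject decision tree assigns each candidate a single reason code.
    Accepted miRNAs are organized into named mature products, seed-sequence
    families, and genomic cistrons with per-sample expression profiles. A
    seeded simulator generates labeled synthetic cohorts so the whole workflow
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
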