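Package: circpipe
Title: Annotation, Expression and Functional-Potential Profiling of Circular RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for characterizing circular RNAs (circRNAs)
    called from backsplice junctions in a multi-population RNA-seq design.
    Classifies junctions against a gene annotation (genic-exonic, genic-other,
    antisense, intergenic), decomposes genic circRNAs into exon and intron
    features, reconstructs mature sequences, quantifies per-feature expression
    as RPKM with a data-derived expression threshold, classifies expression
    trajectories across three cell populations by fold-change thresholds,
    scans mature sequences for miRNA seed sites with Bartel categories and
    score/energy gates, finds open reading frames and scores their codon
    adaptation index against a Markov-model expected-CAI threshold, aggregates
    per-base conservation scores over circRNA bodies and flanks against
    location-matched shuffled backgrounds, and compares circular with linear
    host-gene expression. Ships a synthetic-data generator with a
    machine-readable truth manifest so the whole pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
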