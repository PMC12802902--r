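Package: proteomapr
Title: Proteogenomic Discovery of Noncanonical Proteoforms and PTM Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds custom protein sequence databases from transcript annotations
    for proteogenomic searches, covering N-terminal extensions from near-cognate
    translation-initiation sites, upstream open reading frames, translational
    readthrough of stop codons, and novel splice junctions. Provides in-silico
    tryptic digestion, peptide novelty classification, monoisotopic mass and
    fragment/immonium ion arithmetic, post-search PSM filtering by fragment-ion
    coverage, a 39-class modification registry with PTM landscape summaries,
    single-nucleotide plausibility filtering of readthrough events,
    missing-protein evidence reporting, and mRNA-protein abundance integration.
    A seeded synthetic-data generator with a machine-readable truth ledger
    exercises every step with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
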