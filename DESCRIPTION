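Package: retromethylmap
Title: Copy-Level Retroelement DNA Methylation Analysis for Germ-Cell WGBS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for copy-resolved DNA methylation analysis of
    retrotransposons (SVA, LINE-1, LTR12) in whole-genome bisulfite
    sequencing data from human germ cells. Builds a catalog of full-length
    repeat copies from RepeatMasker annotation, quantifies per-copy
    methylation from Bismark coverage files with depth and CpG-count
    filters, classifies copies into low/medium/high methylation classes and
    two-donor concordance classes, associates classes with KRAB zinc-finger
    protein binding peaks, position-weight-matrix motif content, VNTR unit
    number, genomic context and gene expression, scores simulated-read
    mappability of each copy, refines differentially methylated regions
    between two methylomes, and ships a seeded synthetic-data generator
    with known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
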