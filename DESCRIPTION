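Package: bridgepet
Title: Bridge-Linker Proximity-Ligation Analysis of Chromatin Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying two-step (bridge-linker mediated) versus
    one-step proximity ligation of chromatin fragments. Implements the
    ligation-kinetics ODE systems and their closed-form solutions, in-silico
    restriction digestion and enzyme-targeting profiles, bitap fuzzy search
    for bridge-linker detection in paired-end reads, paired-end-tag (PET)
    formation with duplicate removal and library statistics, downstream
    contact analytics (peak enrichment, fold-change grouping, contact
    matrices, PET clustering into loops, loop classification, CTCF motif
    orientation, virtual 4C), and a ground-truth simulator that emits
    synthetic genomes, planted loops and paired FASTQ libraries carrying the
    bridge linker at ligation junctions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Matrix,
    igraph,
    jsonlite,
    stringi,
    Rcpp,
    methods,
    BiocGenerics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
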