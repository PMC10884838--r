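Package: gcrscope
Title: Detection of Chromosome Terminal Deletions and Their Healing
    Mechanisms from Short-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Read-based detection of gross chromosomal rearrangements
    (GCRs) that delete a chromosome end in small haploid genomes such as
    fission yeast. Computes exact k-mer mappability and unique regions,
    sliding-window normalized read depth and terminal copy-number calls,
    clusters soft-clipped reads to base-resolution junctions,
    characterizes clipped sequence (telomeric repeat content, realignment
    partner, junction microhomology), detects inversions and
    translocations from discordant read pairs, narrows homology-mediated
    breakpoints to their identical-sequence interval, and classifies each
    terminal deletion as a homology-driven translocation, a
    homology-independent fusion, de novo telomere addition, or a complex
    inversion plus deletion. A companion simulator builds toy genomes
    carrying the relevant structural motifs, applies rearrangements with
    recorded truth, and emits paired-end reads with exact truth
    alignments, so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
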