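Package: csbRefine
Title: Nucleotide-Resolution Refinement of Synteny Block Borders and
    Breakpoint Detection
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Refines the borders of computational synteny blocks (CSBs)
    flanking a large-scale genomic rearrangement to nucleotide resolution.
    Given two DNA sequences, a pair of adjacent CSBs and any repeated
    regions between them, the package builds a padded region of interest,
    stretches the blocks and repeats into virtual blocks covering it,
    aligns each virtual block, converts the alignments into
    multi-scale percent-identity profiles and a repeat consensus profile,
    and scans the normalized absolute difference of those profiles with a
    six-state finite-state machine to locate breakpoint intervals. Refined
    block coordinates, breakpoints, proportional adjacent-block control
    regions (PRASB) and inter-breakpoint gap intervals are reported in
    standard tabular, BED and FASTA formats. A seeded simulator generates
    genome pairs with implanted inversions, junction repeats and known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Alignment, ComparativeGenomics, Genetics, Software
RoxygenNote: 7.3.3
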