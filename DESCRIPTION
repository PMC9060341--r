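Package: pairwiseMosaic
Title: Selecting Mosaic Mutations from All-vs-All Pairwise Single-Cell
    Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies somatic variant calls from comprehensive
    clone-to-clone (cell-to-cell) comparisons without a matched bulk.
    Every non-redundant call across all ordered pairwise comparisons of N
    cells is summarised as an NxN binary call matrix; row-like patterns
    indicate mosaic mutations, column-like patterns indicate germline
    variants, and sporadic patterns indicate noise. Mosaic and germline
    scores derived from the matrix place each variant in one of four
    regions (mosaic, germline, high-frequency mosaic, noise). An allele
    dropout analysis mode detects dropout regions from binned
    heterozygous-SNP allele fractions in amplified single cells and
    excludes affected cells from scoring; structural variants are
    supported through reciprocal-overlap clustering. Includes a synthetic
    cohort generator for end-to-end validation and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    rlang,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
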