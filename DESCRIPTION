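Package: quantcap
Title: Design and Quantify Targeted Sequence-Capture Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for quantitative sequence capture (capture-seq) of a
    chosen gene set. Designs tiled fixed-length hybridization bait libraries
    from a genome and GFF3 annotation (promoter/gene-body/terminator capture
    templates on the coding strand, repeat masking, deduplication and an
    exact-match genome specificity filter), quantifies capture-seq alignments
    over the target regions (per-region read counts, breadth of coverage,
    genomic-DNA spike-in QC, negative-control contamination checks), and
    normalizes and explores the resulting count matrices (control-gene
    goodness-of-fit selection, median-of-ratios scaling, log-ratio profiles
    relative to a reference condition, z-score heatmap clustering and
    correlation analysis). Includes a seeded synthetic-data generator that
    emulates a capture-seq study end to end for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
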