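Package: rcrekit
Title: Discovery and Expression Quantification of HERV-K Rec-Responsive Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for locating degenerate copies of the
    HERV-K Rec-responsive element (RcRE) in genome sequences by seeded global
    alignment, annotating hits against gene models and an LTR catalog,
    intersecting FDR-filtered differential-expression gene lists, quantifying
    expression of repetitive proviral loci from stranded paired-end alignments
    with a unique-mapping filter, and testing per-locus enrichment between
    conditions and RNA compartments with median-of-ratios normalization and a
    negative-binomial Wald test. Ships a synthetic-data generator that produces
    genomes with implanted elements, stranded SAM alignments over repetitive
    loci, and count matrices with known ground truth, so every stage of the
    pipeline can be validated against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    BiocGenerics,
    DESeq2,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
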