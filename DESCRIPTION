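Package: ciascore
Title: Chromosomal Imbalance Analysis from Shallow Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genome-wide chromosomal imbalance from shallow (~5M read)
    whole-genome sequencing of urine or tissue cells. Counts uniquely mapped
    reads in fixed 1-Mb genomic bins, corrects GC bias and normalizes against a
    panel-of-normals reference to obtain per-bin relative copy number, and
    summarizes deviation from the diploid state as a single CIA
    (chromosomal imbalance analysis) score: the sum of per-bin
    Z = sqrt(|log2(xi/2)|) values over the 95th-99th percentile rank window.
    Includes ROC-based cutoff selection with diagnostic performance metrics,
    paired-test concordance statistics (Cohen's kappa, exact McNemar, Fisher's
    exact test), and a synthetic-data generator (GC-biased, overdispersed bin
    counts with tumour-fraction-diluted copy-number events) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    methods,
    stats,
    tools,
    utils,
    withr,
    Rsamtools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
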