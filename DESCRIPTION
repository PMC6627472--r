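Package: methdev
Title: Developmental Methylome and Expression-Divergence Analysis for Fungal Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for comparative whole-genome bisulfite
    and RNA-seq analysis across developmental stages of two related fungal
    species. Calls methylated CG sites by a one-sided binomial test against the
    bisulfite non-conversion background with Benjamini-Hochberg correction,
    detects differentially methylated regions with a 1 kb / 200 bp
    sliding-window Fisher's exact test, identifies methylated promoters and
    gene bodies, profiles transposable-element methylation and its relation to
    expression, quantifies expression (TPM), calls differential expression with
    a built-in negative-binomial Wald test, classifies ortholog
    expression-divergence into five classes, and provides hypergeometric GO
    over-representation, Games-Howell post-hoc comparisons and related
    inferential statistics. Includes a seeded synthetic-data generator that
    emulates a bimodal fungal CG methylome with planted differentially
    methylated regions and planted expression-divergence classes, so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
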