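Package: vqfam
Title: Gene-Family Identification, Duplication and Expression Analysis for
    VQ Motif-Containing Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for characterising a plant gene family
    from sequence and locus tables: consensus-motif scanning and typing of
    VQ motif-containing proteins, protein length, molecular weight and
    theoretical isoelectric point, intron/exon structure inference,
    neighbor-joining phylogenies with bootstrap support, ortholog-based
    naming, tandem versus segmental duplication classification with
    subgenome tabulation, and qRT-PCR relative quantification by the
    2^-ddCt method with replicate statistics. Ships a synthetic-family
    simulator with planted ground truth so every stage is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
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
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
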