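Package: rhepipe
Title: Downstream Analysis of Root-Hair Transcriptome Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tidy toolkit for the downstream stages of a root-hair versus
    non-root-hair RNA-seq comparison: RPKM fold-change filtering of
    Cuffdiff-style differential-expression tables, scanning of the degenerate
    Root Hair cis-Element (RHE) consensus over promoters, introns and spliced
    coding sequences of GFF3 gene models, Pearson co-expression network
    construction over an expression compendium with enrichment-guided
    threshold selection, clustering-coefficient (MCODE-style) module mining,
    and hypergeometric Gene Ontology enrichment with the elim correction.
    Includes seeded synthetic-data generators with planted ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
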