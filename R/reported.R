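#' Published reference tables from the root-hair RNA-seq comparison
#'
#' Small plain-text copies of values printed by the original study, shipped
#' for validating the package's arithmetic against published numbers:
#'
#' * `reported_up_genes()` — the 100 most RH-up-regulated genes with their
#'   RH/NRH RPKM values and the printed log2 fold change.
#' * `reported_rhe_hits()` — the distribution of RHE consensus hits across
#'   promoter / intron / CDS regions: region-local start/end positions
#'   (descending for reverse-orientation hits) and the printed hit pattern.
#' * `reported_novel_transcripts()` — the 14 differentially expressed
#'   previously unannotated transcripts (RPKM pairs, printed fold change
#'   with `"inf"` for transcripts undetected in RH, q-values).
#' * `reported_rhe_patterns()` — three additional promoter hit patterns
#'   reported as relatively enriched but not listed in the hit table.
#'
#' Numeric fold-change columns keep the printed text (`log2fc_printed`)
#' because `"inf"` entries and print precision are part of what the
#' validation checks.
#'
#' @return A tibble (or character vector for `reported_rhe_patterns()`).
#' @name reported
NULL

reported_file <- function(name) {
  system.file("extdata", name, package = "rhepipe", mustWork = TRUE)
}

#' @rdname reported
#' @export
reported_up_genes <- function() {
  readr::read_tsv(reported_file("reported_up100.tsv"),
                  col_types = "ccddc", progress = FALSE)
}

#' @rdname reported
#' @export
reported_rhe_hits <- function() {
  readr::read_tsv(reported_file("reported_rhe_hits.tsv"),
                  col_types = "ccciicddc", progress = FALSE)
}

#' @rdname reported
#' @export
reported_novel_transcripts <- function() {
  readr::read_tsv(reported_file("reported_novel_transcripts.tsv"),
                  col_types = "ccddcd", progress = FALSE)
}

#' @rdname reported
#' @export
reported_rhe_patterns <- function() {
  readLines(reported_file("reported_rhe_patterns.txt"))
}
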