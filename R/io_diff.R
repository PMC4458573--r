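#' Column mappings for differential-expression tables
#'
#' A differential-expression table needs five columns: the gene identifier,
#' the RPKM abundance in each of the two compared conditions (root hair, RH,
#' and non-root-hair, NRH), the FDR-adjusted p-value (q-value) and the test
#' status.  `diff_cols()` returns the package's canonical header vocabulary;
#' `cuffdiff_cols()` maps the vocabulary of Cuffdiff's `gene_exp.diff`
#' output (`value_1`/`value_2`/`q_value`/`status`).  Pass either (or your
#' own named vector with these five names) to [read_diff_table()].
#'
#' @return Named character vector mapping canonical field names
#'   (`gene_id`, `rpkm_rh`, `rpkm_nrh`, `q_value`, `status`) to file headers.
#' @export
#' @examples
#' diff_cols()
#' cuffdiff_cols()
diff_cols <- function() {
  c(gene_id = "gene_id", annotation = "annotation",
    rpkm_rh = "rpkm_rh", rpkm_nrh = "rpkm_nrh",
    q_value = "q_value", status = "status")
}

#' @rdname diff_cols
#' @export
cuffdiff_cols <- function() {
  c(gene_id = "gene_id", annotation = "gene",
    rpkm_rh = "value_1", rpkm_nrh = "value_2",
    q_value = "q_value", status = "status")
}

parse_strict_double <- function(x, column) {
  x[x == "."] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L) {
    stop_rhe(sprintf("column `%s` has non-numeric value '%s' (row %d)",
                     column, x[bad[1L]], bad[1L]), "bad_value")
  }
  out
}

#' Read a Cuffdiff-style differential-expression table
#'
#' Reads a tab-delimited per-gene table with RPKM abundances in root hairs
#' (RH) and non-root-hair tissues (NRH), a q-value and a status flag, and
#' derives the log2 fold change `log2(rpkm_nrh / rpkm_rh)` for every row
#' (see [log2_fold_change()] for the sign and infinity conventions).
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param col_map Named character vector locating the required columns in the
#'   file header; see [diff_cols()].  The `annotation` entry is optional in
#'   the file.  If a mapped canonical header is absent the Cuffdiff
#'   vocabulary of [cuffdiff_cols()] is tried as a fallback.
#' @return A tibble with columns `gene_id`, `annotation`, `rpkm_rh`,
#'   `rpkm_nrh`, `q_value`, `status`, `log2fc`, one row per gene.
#' @export
read_diff_table <- function(path, col_map = diff_cols()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = ".", progress = FALSE)
  fallback <- cuffdiff_cols()
  locate <- function(field, required = TRUE) {
    for (cand in unique(c(col_map[[field]], fallback[[field]]))) {
      if (!is.null(cand) && !is.na(cand) && cand %in% names(raw)) return(cand)
    }
    if (required) {
      stop_rhe(sprintf("required column `%s` (mapped to '%s') is missing",
                       field, col_map[[field]]), "missing_column")
    }
    NA_character_
  }
  gene_col <- locate("gene_id")
  ann_col <- locate("annotation", required = FALSE)
  tbl <- tibble(
    gene_id = raw[[gene_col]],
    annotation = if (is.na(ann_col)) NA_character_ else raw[[ann_col]],
    rpkm_rh = parse_strict_double(raw[[locate("rpkm_rh")]], "rpkm_rh"),
    rpkm_nrh = parse_strict_double(raw[[locate("rpkm_nrh")]], "rpkm_nrh"),
    q_value = parse_strict_double(raw[[locate("q_value")]], "q_value"),
    status = raw[[locate("status")]]
  )
  validate_diff_table(tbl)
  tbl$log2fc <- log2_fold_change(tbl$rpkm_rh, tbl$rpkm_nrh,
                                 allow_both_zero = TRUE)
  tbl
}

validate_diff_table <- function(tbl) {
  dup <- tbl$gene_id[duplicated(tbl$gene_id)]
  if (length(dup) > 0L) {
    stop_rhe(sprintf("duplicate gene id: %s", dup[1L]), "duplicate_gene")
  }
  if (any(stats::na.omit(tbl$rpkm_rh) < 0) ||
      any(stats::na.omit(tbl$rpkm_nrh) < 0)) {
    stop_rhe("RPKM values must be >= 0", "bad_value")
  }
  q <- stats::na.omit(tbl$q_value)
  if (any(q < 0 | q > 1)) {
    stop_rhe("q-values must lie in [0, 1]", "bad_value")
  }
  invisible(tbl)
}

#' Write a differential-expression table
#'
#' Inverse of [read_diff_table()]: tab-delimited, canonical headers, `.` for
#' missing values.  The derived `log2fc` column is not written (it is
#' recomputed on read).
#'
#' @param tbl Tibble as returned by [read_diff_table()] or [gen_diff_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(tbl, path) {
  out <- tbl[, intersect(names(diff_cols()), names(tbl))]
  write_tsv_dot(out, path)
}

# Shared TSV writer: "\t" separated, "." for NA, no quoting.
write_tsv_dot <- function(tbl, path) {
  tbl <- dplyr::mutate(tbl, dplyr::across(
    dplyr::where(is.numeric), ~ ifelse(is.na(.x), NA, format(.x, digits = 15,
                                                             trim = TRUE,
                                                             scientific = FALSE))))
  readr::write_tsv(tbl, path, na = ".", progress = FALSE)
  invisible(path)
}
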