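#' RPKM from raw counts
#'
#' Reads Per Kilobase of transcript per Million mapped reads:
#' `1e9 * read_count / (gene_length_bp * total_mapped_reads)`.
#'
#' @param read_count Number of reads assigned to the gene (vectorised).
#' @param gene_length_bp Transcript length in bp (> 0).
#' @param total_mapped_reads Library size (> 0).
#' @return Numeric RPKM values.
#' @export
#' @examples
#' compute_rpkm(1000, 2000, 1e7)  # 50
compute_rpkm <- function(read_count, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp <= 0)) {
    stop_rhe("gene_length_bp must be > 0", "bad_argument")
  }
  if (any(total_mapped_reads <= 0)) {
    stop_rhe("total_mapped_reads must be > 0", "bad_argument")
  }
  1e9 * read_count / (gene_length_bp * total_mapped_reads)
}

#' Log2 fold change of two RPKM values
#'
#' The study's convention: `log2(rpkm_nrh / rpkm_rh)`.  Genes enriched in
#' root hairs therefore carry *negative* values.  When one abundance is zero
#' the ratio degenerates: `+Inf` iff `rpkm_rh == 0` and `rpkm_nrh > 0`
#' (detected only outside root hairs), `-Inf` for the mirror case (detected
#' only in root hairs, printed as "inf" magnitude in the study's tables).
#'
#' @param rpkm_rh,rpkm_nrh Non-negative abundances (vectorised).
#' @param allow_both_zero If `TRUE`, rows with both abundances zero yield
#'   `NA` instead of an error (used when deriving the column for whole
#'   tables that may contain silent genes).
#' @return Numeric vector (may contain `+/-Inf`).
#' @export
#' @examples
#' log2_fold_change(282.55, 0.145177)  # -10.93, strongly RH-enriched
log2_fold_change <- function(rpkm_rh, rpkm_nrh, allow_both_zero = FALSE) {
  if (any(rpkm_rh < 0, na.rm = TRUE) || any(rpkm_nrh < 0, na.rm = TRUE)) {
    stop_rhe("RPKM values must be >= 0", "bad_argument")
  }
  both_zero <- rpkm_rh == 0 & rpkm_nrh == 0
  if (any(both_zero, na.rm = TRUE) && !allow_both_zero) {
    stop_rhe("log2 fold change undefined when both RPKM are 0", "bad_argument")
  }
  out <- log2(rpkm_nrh / rpkm_rh)
  out[rpkm_rh == 0 & rpkm_nrh > 0] <- Inf
  out[rpkm_nrh == 0 & rpkm_rh > 0] <- -Inf
  out[both_zero] <- NA_real_
  out
}

#' Differential-expression filter criteria
#'
#' The three-rule filter of the study: (1) q-value strictly below `q_max`;
#' (2) fold change strictly greater than `min_fold` in either direction
#' (`|log2fc| > log2(min_fold)`, infinities pass); (3) RPKM strictly greater
#' than `min_rpkm_either` in at least one condition.  All comparisons are
#' strict, per the wording "less than" / "greater than" / "more than".
#'
#' @param q_max Maximum q-value (default 0.05).
#' @param min_fold Minimum fold ratio (default 2).
#' @param min_rpkm_either Minimum RPKM in at least one condition (default 1).
#' @return A list of class `de_criteria`.
#' @export
de_criteria <- function(q_max = 0.05, min_fold = 2, min_rpkm_either = 1) {
  assert_scalar_number(q_max, "q_max", lower = 0)
  assert_scalar_number(min_fold, "min_fold", lower = 0)
  assert_scalar_number(min_rpkm_either, "min_rpkm_either", lower = 0)
  structure(list(q_max = q_max, min_fold = min_fold,
                 min_rpkm_either = min_rpkm_either),
            class = "de_criteria")
}

#' Apply the differential-expression filter
#'
#' Evaluates the three criteria of [de_criteria()] on every row and assigns
#' passing genes to a direction by the sign of `log2fc = log2(nrh/rh)`:
#' negative (including `-Inf`) means up-regulated in root hairs.
#'
#' @param tbl Diff table with columns `gene_id`, `rpkm_rh`, `rpkm_nrh`,
#'   `q_value`, `status` and (optionally precomputed) `log2fc`.
#' @param criteria A [de_criteria()] object.
#' @param require_ok If `TRUE` (default) only rows with status `"OK"` are
#'   eligible, mirroring the "confidently identified" convention of the
#'   upstream test.
#' @return Tibble of passing rows with a `direction` column
#'   (`"up_in_rh"` / `"up_in_nrh"`).  Use [de_partition()] for the bare id
#'   sets.
#' @export
filter_de <- function(tbl, criteria = de_criteria(), require_ok = TRUE) {
  stopifnot(inherits(criteria, "de_criteria"))
  if (nrow(tbl) == 0L) {
    return(dplyr::mutate(tbl, direction = character(0)))
  }
  lfc <- if ("log2fc" %in% names(tbl)) tbl$log2fc else {
    log2_fold_change(tbl$rpkm_rh, tbl$rpkm_nrh, allow_both_zero = TRUE)
  }
  pass <- !is.na(tbl$q_value) & tbl$q_value < criteria$q_max &
    !is.na(lfc) & abs(lfc) > log2(criteria$min_fold) &
    pmax(tbl$rpkm_rh, tbl$rpkm_nrh) > criteria$min_rpkm_either
  if (require_ok) pass <- pass & tbl$status == "OK"
  out <- tbl[pass, , drop = FALSE]
  out$log2fc <- lfc[pass]
  out$direction <- ifelse(out$log2fc < 0, "up_in_rh", "up_in_nrh")
  as_tibble(out)
}

#' @rdname filter_de
#' @param de Output of `filter_de()`.
#' @export
de_partition <- function(de) {
  list(up_in_rh = de$gene_id[de$direction == "up_in_rh"],
       up_in_nrh = de$gene_id[de$direction == "up_in_nrh"])
}

#' Genes detected only in root hairs
#'
#' A gene is "RH-only" when its NRH abundance is exactly zero (the upstream
#' pipeline prints an infinite fold change for these) and its RH abundance
#' is at least `min_rpkm`.
#'
#' @param tbl Diff table.
#' @param min_rpkm Minimum RH abundance (default 1).
#' @return Character vector of gene ids.
#' @export
rh_only_genes <- function(tbl, min_rpkm = 1) {
  tbl$gene_id[tbl$rpkm_nrh == 0 & tbl$rpkm_rh >= min_rpkm]
}

#' Overlap statistics between two gene sets
#'
#' Percentages are rounded to the nearest integer, halves away from zero
#' (the published roundings are not internally consistent, so the package
#' fixes one convention).  An empty denominator yields `NA`.
#'
#' @param set_a,set_b Character vectors of ids.
#' @return One-row tibble: `n_a`, `n_b`, `n_overlap`, `pct_of_a`, `pct_of_b`.
#' @export
#' @examples
#' overlap_stats(paste0("g", 1:635), paste0("g", 1:580))$pct_of_a  # 91
overlap_stats <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  n_ov <- length(intersect(set_a, set_b))
  pct <- function(num, den) {
    if (den == 0L) return(NA_real_)
    round_half_away(100 * num / den)
  }
  tibble(n_a = length(set_a), n_b = length(set_b), n_overlap = n_ov,
         pct_of_a = pct(n_ov, length(set_a)),
         pct_of_b = pct(n_ov, length(set_b)))
}

# round() in R rounds halves to even; the package convention is half away
# from zero.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Flag merged loci absent from a reference annotation
#'
#' A merged locus is "novel" when its exonic span overlaps no reference gene
#' span on the same chromosome (strand-agnostic; any overlap, even 1 bp,
#' disqualifies).
#'
#' @param merged_models,reference_models Gene-model tibbles
#'   (see [read_gff3()]).
#' @return Character vector of novel `gene_id`s from `merged_models`.
#' @export
flag_novel_loci <- function(merged_models, reference_models) {
  span_tbl <- function(models) {
    dplyr::summarise(
      dplyr::group_by(
        dplyr::mutate(models,
                      start = purrr::map_int(.data$exons, ~ min(.x[, 1L])),
                      end = purrr::map_int(.data$exons, ~ max(.x[, 2L]))),
        .data$gene_id, .data$chrom),
      start = min(.data$start), end = max(.data$end), .groups = "drop")
  }
  merged <- span_tbl(merged_models)
  ref <- span_tbl(reference_models)
  novel <- purrr::map_lgl(seq_len(nrow(merged)), function(i) {
    r <- ref[ref$chrom == merged$chrom[i], ]
    if (nrow(r) == 0L) return(TRUE)
    !any(r$start <= merged$end[i] & merged$start[i] <= r$end)
  })
  unique(merged$gene_id[novel])
}

#' Cluster genes by expression pattern
#'
#' Hierarchical agglomeration with distance `1 - Pearson r` across the
#' compendium arrays, average linkage, tree cut into `k` groups — the
#' procedure behind "grouped into nine clusters according to expression
#' patterns".  Zero-variance genes cannot be correlated and are dropped with
#' a warning.
#'
#' @param genes Character vector of gene ids to cluster.
#' @param mat Compendium matrix (genes x arrays), e.g. from
#'   [gen_compendium()] or [read_compendium()].
#' @param k Number of clusters (must not exceed the number of usable genes).
#' @return Tibble with columns `gene_id`, `cluster` (integer labels 1..k).
#' @export
cluster_expression_patterns <- function(genes, mat, k) {
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0L) {
    stop_rhe(sprintf("gene not in compendium: %s", missing[1L]), "bad_argument")
  }
  sub <- mat[genes, , drop = FALSE]
  vars <- apply(sub, 1L, stats::var)
  if (any(vars == 0)) {
    warn(sprintf("dropping %d constant-expression gene(s) from clustering",
                 sum(vars == 0)))
    sub <- sub[vars > 0, , drop = FALSE]
  }
  if (k > nrow(sub)) {
    stop_rhe("k exceeds the number of usable genes", "bad_argument")
  }
  d <- as.dist(1 - cor(t(sub)))
  hc <- hclust(d, method = "average")
  tibble(gene_id = rownames(sub),
         cluster = as.integer(cutree(hc, k = k)))
}
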