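#' Write and read motif-hit tables
#'
#' `write_hits()`/`read_hits()` round-trip the full hit table (gene, region
#' class, intron ordinal, 1-based region-local start/end, orientation and
#' matched sequence; reverse-orientation hits have `start > end`).
#' `write_hits_bed()` additionally exports a BED-like view with 0-based
#' half-open coordinates (`bed_start = min(start, end) - 1`,
#' `bed_end = max(start, end)`), one-way, for genome-browser style tooling.
#'
#' @param hits Tibble of hits as returned by [scan_gene()].
#' @param path Output path.
#' @return The written path (writers, invisibly) or a hit tibble (reader).
#' @export
write_hits <- function(hits, path) {
  cols <- c("gene_id", "region", "region_index", "start", "end",
            "orientation", "matched_seq")
  write_tsv_dot(hits[, cols], path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", region = "c", region_index = "i",
    start = "i", end = "i", orientation = "c", matched_seq = "c"
  ), na = ".", progress = FALSE)
}

#' @rdname write_hits
#' @export
write_hits_bed <- function(hits, path) {
  bed <- tibble(
    chrom = paste0(hits$gene_id, ":", hits$region,
                   ifelse(hits$region == "intron", hits$region_index, "")),
    bed_start = pmin(hits$start, hits$end) - 1L,
    bed_end = pmax(hits$start, hits$end),
    name = hits$matched_seq,
    score = 0L,
    strand = hits$orientation
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write and read co-expression networks
#'
#' The edge list is written as a tab-delimited file (`from`, `to`, `weight`)
#' with the network threshold preserved in a `# threshold:` comment header;
#' node attributes (id, degree) go to a companion file when `nodes_path` is
#' given.  `read_network()` restores an equal network object.
#'
#' @param network A `coexpression_network` (see [build_network()]).
#' @param path Edge-list path.
#' @param nodes_path Optional node-attribute path.
#' @return The written path (writer, invisibly) or a network (reader).
#' @export
write_network <- function(network, path, nodes_path = NULL) {
  con <- file(path, "w")
  writeLines(sprintf("# threshold: %s",
                     format(network$threshold, digits = 15)), con)
  close(con)
  readr::write_tsv(
    dplyr::mutate(network$edges,
                  weight = format(.data$weight, digits = 15, trim = TRUE)),
    path, append = TRUE, col_names = TRUE, progress = FALSE
  )
  if (!is.null(nodes_path)) {
    deg <- network_degrees(network)
    write_tsv_dot(deg, nodes_path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  first <- readLines(path, n = 1L)
  threshold <- as.numeric(sub("^# threshold: ", "", first))
  edges <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    from = "c", to = "c", weight = "d"
  ), progress = FALSE)
  new_network(edges, threshold = threshold,
              n_input_genes = length(unique(c(edges$from, edges$to))))
}

#' Write enrichment results
#'
#' Tab-delimited, sorted ascending by p-value (`p_elim` when present,
#' otherwise `p_classic`); ties by term id.
#'
#' @param results Enrichment tibble from [classic_enrichment()] or
#'   [elim_enrichment()].
#' @param path Output path.
#' @return The written path (writer, invisibly) or a tibble (reader).
#' @export
write_enrichment <- function(results, path) {
  key <- if ("p_elim" %in% names(results)) results$p_elim else results$p_classic
  out <- results[order(key, results$term_id), ]
  write_tsv_dot(out, path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  readr::read_tsv(path, na = ".", col_types = readr::cols(
    term_id = "c", name = "c", .default = "d"
  ), progress = FALSE)
}

#' Write / read one-id-per-line gene sets
#'
#' @param ids Character vector of gene ids.
#' @param path File path.
#' @return The path (writer, invisibly) or a character vector (reader).
#' @export
write_gene_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  readLines(path)
}
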