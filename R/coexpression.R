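#' Pearson correlation of two expression profiles
#'
#' Thin validated wrapper around the product-moment coefficient; errors on
#' unequal lengths, fewer than 3 arrays, or zero variance (where the
#' coefficient is undefined).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_rhe("profiles must have equal length >= 3", "bad_argument")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_rhe("correlation undefined for zero-variance profile", "zero_variance")
  }
  cor(x, y)
}

new_network <- function(edges, threshold, n_input_genes) {
  edges <- as_tibble(edges)
  structure(
    list(edges = edges,
         nodes = sort(unique(c(edges$from, edges$to))),
         threshold = threshold,
         n_input_genes = n_input_genes),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "<coexpression_network> %d nodes (from %d input genes), %d edges, r >= %s\n",
    length(x$nodes), x$n_input_genes, nrow(x$edges), format(x$threshold)))
  invisible(x)
}

network_degrees <- function(network) {
  all_ends <- c(network$edges$from, network$edges$to)
  tab <- table(factor(all_ends, levels = network$nodes))
  tibble(node = network$nodes, degree = as.integer(tab))
}

# Correlation-thresholded edge list over a gene subset; pairs stored
# canonically (from < to).
edges_at_threshold <- function(cmat, threshold) {
  idx <- which(upper.tri(cmat) & cmat >= threshold, arr.ind = TRUE)
  f <- rownames(cmat)[idx[, 1L]]
  t <- colnames(cmat)[idx[, 2L]]
  swap <- f > t
  edges <- tibble(
    from = ifelse(swap, t, f),
    to = ifelse(swap, f, t),
    weight = cmat[idx]
  )
  dplyr::arrange(edges, .data$from, .data$to)
}

#' Build a Pearson co-expression network
#'
#' Connects gene pairs whose Pearson correlation across the compendium
#' arrays is at least `threshold` (the study's headline cutoff is 0.83).
#' Genes left without any retained edge are not nodes — matching the
#' "122 nodes from 124 genes" convention — but the raw input count is kept
#' alongside.
#'
#' @param mat Compendium matrix, genes in rows, arrays in columns.
#' @param genes Gene ids to include (must be rows of `mat`).
#' @param threshold Correlation cutoff in `[-1, 1]`.
#' @return A `coexpression_network`: canonical edge tibble
#'   (`from < to`, `weight` = r), node vector, threshold and input-gene
#'   count.
#' @export
build_network <- function(mat, genes = rownames(mat), threshold = 0.83) {
  assert_scalar_number(threshold, "threshold", lower = -1, upper = 1)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0L) {
    stop_rhe(sprintf("gene not in compendium: %s", missing[1L]), "bad_argument")
  }
  if (ncol(mat) < 3L) {
    stop_rhe("need >= 3 arrays for correlation", "bad_argument")
  }
  genes <- unique(genes)
  sub <- mat[genes, , drop = FALSE]
  keep <- apply(sub, 1L, stats::sd) > 0
  cmat <- suppressWarnings(cor(t(sub[keep, , drop = FALSE])))
  edges <- if (sum(keep) >= 2L) edges_at_threshold(cmat, threshold) else {
    tibble(from = character(0), to = character(0), weight = numeric(0))
  }
  new_network(edges, threshold = threshold, n_input_genes = length(genes))
}

#' Connected components of a network
#'
#' @param network A `coexpression_network`.
#' @return List of character vectors (node sets), ordered by decreasing
#'   size, ties broken by the lexicographically smallest member; each set is
#'   sorted.
#' @export
connected_components <- function(network) {
  if (nrow(network$edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(network$edges[, c("from", "to")],
                                     directed = FALSE)
  memb <- igraph::components(g)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort)
  ord <- order(-vapply(comps, length, integer(1)),
               vapply(comps, `[[`, character(1), 1L))
  unname(comps[ord])
}

#' Select the correlation threshold by a GO-enrichment sweep
#'
#' For each candidate threshold a network is built and a classic
#' hypergeometric enrichment of its node set (against the full input gene
#' set as population) is run; the score is the number of GO terms with
#' `p < sweep_alpha`.  The chosen threshold maximises the score, ties broken
#' upward — operationalising "the threshold with the best enrichments of GO
#' categories" over the study's 0.7-0.9 series.
#'
#' @param mat Compendium matrix.
#' @param genes Input gene set.
#' @param dag A `go_dag` with annotations covering the genes.
#' @param grid Candidate thresholds (default `seq(0.70, 0.90, by = 0.01)`).
#' @param sweep_alpha Significance cutoff counted as "enriched"
#'   (default 1e-3).
#' @param statistic `"count"` (default) scores a threshold by the number of
#'   terms below `sweep_alpha`; `"min_p"` scores by `-log10` of the smallest
#'   p-value.
#' @return A list of class `sweep_result`: per-threshold tibble
#'   (`threshold`, `n_nodes`, `n_edges`, `score`) and the `chosen` value.
#' @export
select_threshold <- function(mat, genes, dag,
                             grid = seq(0.70, 0.90, by = 0.01),
                             sweep_alpha = 1e-3,
                             statistic = c("count", "min_p")) {
  statistic <- match.arg(statistic)
  if (length(grid) == 0L) stop_rhe("threshold grid is empty", "bad_argument")
  grid <- sort(grid)
  rows <- purrr::map(grid, function(th) {
    net <- build_network(mat, genes, threshold = th)
    score <- if (length(net$nodes) == 0L) 0 else {
      enr <- classic_enrichment(dag, study = net$nodes, population = genes)
      if (statistic == "count") sum(enr$p_classic < sweep_alpha)
      else if (nrow(enr) == 0L) 0 else -log10(min(enr$p_classic))
    }
    tibble(threshold = th, n_nodes = length(net$nodes),
           n_edges = nrow(net$edges), score = score)
  })
  tbl <- dplyr::bind_rows(rows)
  if (all(tbl$n_edges == 0L)) {
    stop_rhe("all candidate networks are empty; lower the threshold grid",
             "empty_sweep")
  }
  best <- max(tbl$score)
  chosen <- max(tbl$threshold[tbl$score == best])
  structure(list(sweep = tbl, chosen = chosen, sweep_alpha = sweep_alpha,
                 statistic = statistic),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d thresholds, chosen r >= %.2f\n",
              nrow(x$sweep), x$chosen))
  invisible(x)
}

#' Build a bait-prey co-expression network
#'
#' All bait-bait, bait-prey and prey-prey correlations at `threshold` are
#' computed, then every prey-prey edge is discarded ("discarding edges only
#' linked to two preys") and nodes left isolated are dropped, so every
#' retained prey has at least one bait neighbour.
#'
#' @param mat Compendium matrix.
#' @param baits,preys Disjoint gene-id vectors.
#' @param threshold Correlation cutoff.
#' @return A `coexpression_network` whose edge tibble gains a `kind` column
#'   (`"bait-bait"` / `"bait-prey"`), plus a `roles` tibble attribute-style
#'   element mapping retained nodes to `"bait"`/`"prey"`.
#' @export
bait_prey_network <- function(mat, baits, preys, threshold = 0.83) {
  baits <- unique(baits)
  preys <- unique(preys)
  if (length(intersect(baits, preys)) > 0L) {
    stop_rhe("baits and preys must be disjoint", "bad_argument")
  }
  net <- build_network(mat, c(baits, preys), threshold = threshold)
  e <- net$edges
  from_bait <- e$from %in% baits
  to_bait <- e$to %in% baits
  e <- e[from_bait | to_bait, , drop = FALSE]
  e$kind <- ifelse(e$from %in% baits & e$to %in% baits,
                   "bait-bait", "bait-prey")
  out <- new_network(e, threshold = threshold,
                     n_input_genes = length(baits) + length(preys))
  out$roles <- tibble(node = out$nodes,
                      role = ifelse(out$nodes %in% baits, "bait", "prey"))
  out
}

#' @rdname tidy_rhepipe
#' @export
tidy.coexpression_network <- function(x, ...) {
  x$edges
}

#' Tidiers for rhepipe result objects
#'
#' `tidy()` returns the per-element table (edges for a network, the sweep
#' table for a threshold sweep); `glance()` returns a one-row summary.
#'
#' @param x A `coexpression_network` or `sweep_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_rhepipe
#' @export
glance.coexpression_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         n_input_genes = x$n_input_genes, threshold = x$threshold,
         n_components = length(connected_components(x)))
}

#' @rdname tidy_rhepipe
#' @export
tidy.sweep_result <- function(x, ...) {
  x$sweep
}

#' @rdname tidy_rhepipe
#' @export
glance.sweep_result <- function(x, ...) {
  tibble(chosen = x$chosen, sweep_alpha = x$sweep_alpha,
         statistic = x$statistic, best_score = max(x$sweep$score))
}

#' Read / write a gene-by-array expression compendium
#'
#' Tab-delimited matrix: first column `gene_id`, remaining columns one per
#' array, log-scale intensities, no missing values.
#'
#' @param path File path.
#' @return `read_compendium()`: numeric matrix with gene rownames.
#' @export
read_compendium <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "d"), progress = FALSE)
  m <- as.matrix(tbl[, -1L])
  rownames(m) <- tbl$gene_id
  if (anyNA(m)) stop_rhe("compendium contains missing values", "bad_value")
  if (ncol(m) < 3L) stop_rhe("need >= 3 arrays", "bad_argument")
  m
}

#' @rdname read_compendium
#' @param mat Numeric matrix with gene rownames.
#' @export
write_compendium <- function(mat, path) {
  tbl <- dplyr::bind_cols(tibble(gene_id = rownames(mat)),
                          as_tibble(mat, .name_repair = "minimal"))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
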