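#' Hypergeometric upper-tail probability
#'
#' `P[X >= x]` where `X` counts annotated genes in a study sample of size
#' `M` drawn without replacement from a population of `N` genes of which
#' `K` are annotated.  Computed exactly via the hypergeometric distribution.
#'
#' @param x Observed annotated study genes.
#' @param M Study-set size.
#' @param K Annotated genes in the population.
#' @param N Population size.
#' @return The one-sided over-representation p-value.
#' @export
#' @examples
#' hypergeom_upper(3, 5, 5, 20)  # 1126/15504
hypergeom_upper <- function(x, M, K, N) {
  ok <- x >= 0 & M >= 0 & K >= 0 & x <= M & M <= N & K <= N & x <= K
  if (!all(ok)) {
    stop_rhe("impossible hypergeometric counts (need 0 <= x <= min(M, K), M <= N, K <= N)",
             "bad_argument")
  }
  phyper(x - 1, K, N - K, M, lower.tail = FALSE)
}

#' Elim enrichment configuration
#'
#' @param alpha_elim Significance cutoff that triggers gene removal during
#'   the elim walk (default 0.01, the topGO default; the study states only
#'   its reporting cutoffs).
#' @param report_alpha Reporting cutoff attached to results for downstream
#'   filtering (the study uses 1e-3 for network gene sets and 0.01 for the
#'   61-gene set).
#' @return A list of class `elim_config`.
#' @export
elim_config <- function(alpha_elim = 0.01, report_alpha = 0.01) {
  assert_scalar_number(alpha_elim, "alpha_elim", lower = 0, upper = 1)
  assert_scalar_number(report_alpha, "report_alpha", lower = 0, upper = 1)
  structure(list(alpha_elim = alpha_elim, report_alpha = report_alpha),
            class = "elim_config")
}

# term -> character vector of annotated genes (propagated), restricted to
# the population.
term_gene_sets <- function(dag, population) {
  ann <- dag$annotation[dag$annotation$gene_id %in% population, ]
  split(ann$gene_id, ann$term_id)
}

#' Classic hypergeometric GO enrichment
#'
#' Tests every term annotating at least one study gene for
#' over-representation of the study set within the population, using the
#' propagated (true-path) annotations.  No multiple-testing correction is
#' applied; the study reports raw p-values.
#'
#' @param dag A `go_dag`.
#' @param study Character vector of study gene ids (subset of `population`).
#' @param population Character vector of population gene ids.
#' @return Tibble sorted by `p_classic`: `term_id`, `name`, `x` (study
#'   hits), `M` (study size), `K` (population hits), `N` (population size),
#'   `p_classic`.
#' @export
classic_enrichment <- function(dag, study, population) {
  study <- unique(study)
  population <- unique(population)
  if (length(study) == 0L) stop_rhe("study set is empty", "bad_argument")
  if (!all(study %in% population)) {
    stop_rhe("study must be a subset of population", "bad_argument")
  }
  sets <- term_gene_sets(dag, population)
  M <- length(study)
  N <- length(population)
  rows <- purrr::imap(sets, function(genes, term) {
    x <- sum(study %in% genes)
    if (x == 0L) return(NULL)
    tibble(term_id = term, x = x, M = M, K = length(genes), N = N,
           p_classic = hypergeom_upper(x, M, length(genes), N))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(term_id = character(0), name = character(0),
                  x = integer(0), M = integer(0), K = integer(0),
                  N = integer(0), p_classic = numeric(0)))
  }
  out <- dplyr::left_join(out, dag$terms, by = "term_id")
  out <- out[, c("term_id", "name", "x", "M", "K", "N", "p_classic")]
  dplyr::arrange(out, .data$p_classic, .data$term_id)
}

#' Elim GO enrichment
#'
#' The elim correction walks the ontology from its most specific terms
#' upward (levels defined by longest path from the root, deepest first,
#' ties by term id).  Each term is tested on its *current* annotation set;
#' when a term comes out significant (`p < alpha_elim`) its annotated genes
#' are removed from the annotation sets of all its ancestors before those
#' are tested.  This stops specific signal from inflating general parent
#' terms.  With `alpha_elim = 0` nothing is ever removed and the result
#' equals [classic_enrichment()].
#'
#' @inheritParams classic_enrichment
#' @param config An [elim_config()].
#' @return Tibble sorted by `p_elim`: classic columns plus `x_elim`,
#'   `K_elim` (counts after removal) and `p_elim`.
#' @export
elim_enrichment <- function(dag, study, population, config = elim_config()) {
  study <- unique(study)
  population <- unique(population)
  if (length(study) == 0L) stop_rhe("study set is empty", "bad_argument")
  if (!all(study %in% population)) {
    stop_rhe("study must be a subset of population", "bad_argument")
  }
  sets <- term_gene_sets(dag, population)
  terms <- names(sets)
  depths <- dag$depths[terms]
  order_idx <- order(-depths, terms)
  M <- length(study)
  N <- length(population)
  removed <- setNames(vector("list", length(terms)), terms)
  rows <- vector("list", length(terms))
  for (k in order_idx) {
    term <- terms[k]
    cur <- setdiff(sets[[term]], removed[[term]])
    x_e <- sum(study %in% cur)
    K_e <- length(cur)
    p_e <- if (K_e == 0L) 1 else hypergeom_upper(x_e, M, K_e, N)
    x_c <- sum(study %in% sets[[term]])
    K_c <- length(sets[[term]])
    rows[[k]] <- tibble(
      term_id = term, x = x_c, M = M, K = K_c, N = N,
      p_classic = hypergeom_upper(x_c, M, K_c, N),
      x_elim = x_e, K_elim = K_e, p_elim = p_e
    )
    if (p_e < config$alpha_elim) {
      for (anc in intersect(dag$ancestors[[term]], terms)) {
        removed[[anc]] <- unique(c(removed[[anc]], cur))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[out$x > 0L, , drop = FALSE]
  out <- dplyr::left_join(out, dag$terms, by = "term_id")
  out <- out[, c("term_id", "name", "x", "M", "K", "N", "p_classic",
                 "x_elim", "K_elim", "p_elim")]
  dplyr::arrange(out, .data$p_elim, .data$term_id)
}
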