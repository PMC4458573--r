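#' Clustering-coefficient vertex weights
#'
#' For each node i with neighbourhood size Ki and n edges among those
#' neighbours, the clustering coefficient is `Ci = 2 n / (Ki (Ki - 1))`
#' (0 for Ki < 2).  The vertex weight used for module seeding equals Ci —
#' the plain coefficient, which is what the study describes (the original
#' MCODE publication scales it by the k-core number; that variant is not
#' implemented here).
#'
#' @param network A `coexpression_network`.
#' @return Tibble with columns `node`, `ki` (degree), `n_edges` (edges among
#'   neighbours), `ci`, `weight` (= `ci`), sorted by node id.
#' @export
vertex_weights <- function(network) {
  adj <- adjacency_sets(network)
  nodes <- names(adj)
  if (length(nodes) == 0L) {
    return(tibble(node = character(0), ki = integer(0), n_edges = integer(0),
                  ci = numeric(0), weight = numeric(0)))
  }
  rows <- purrr::map(nodes, function(v) {
    nb <- adj[[v]]
    ki <- length(nb)
    if (ki < 2L) {
      return(tibble(node = v, ki = ki, n_edges = 0L, ci = 0))
    }
    n_e <- sum(vapply(nb, function(u) {
      sum(adj[[u]] %in% nb)
    }, numeric(1))) / 2
    tibble(node = v, ki = ki, n_edges = as.integer(n_e),
           ci = 2 * n_e / (ki * (ki - 1)))
  })
  out <- dplyr::bind_rows(rows)
  out$weight <- out$ci
  dplyr::arrange(out, .data$node)
}

adjacency_sets <- function(network) {
  nodes <- network$nodes
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  for (i in seq_len(nrow(network$edges))) {
    a <- network$edges$from[i]
    b <- network$edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

#' Module-mining configuration
#'
#' @param weight_ratio_min A neighbour j joins a module grown from `seed`
#'   iff `weight(j) / weight(seed)` strictly exceeds this ratio
#'   (default 0.1, the study's "Wj/Wseed > 0.1").
#' @param min_degree Modules whose induced subgraph has minimum degree below
#'   this are discarded (the study leaves the value unstated; default 2).
#' @param min_nodes Minimum module size (default 6, i.e. "node count > 5").
#' @return A list of class `module_config`.
#' @export
module_config <- function(weight_ratio_min = 0.1, min_degree = 2L,
                          min_nodes = 6L) {
  assert_scalar_number(weight_ratio_min, "weight_ratio_min", lower = 0,
                       upper = 1)
  assert_scalar_number(min_degree, "min_degree", lower = 0)
  assert_scalar_number(min_nodes, "min_nodes", lower = 1)
  structure(list(weight_ratio_min = weight_ratio_min,
                 min_degree = as.integer(min_degree),
                 min_nodes = as.integer(min_nodes)),
            class = "module_config")
}

#' Grow one module from a seed node
#'
#' Breadth-first outward expansion: a neighbour joins iff its weight ratio
#' to the seed strictly exceeds `config$weight_ratio_min`; joined nodes'
#' neighbours are examined in turn, each node visited once.  Traversal order
#' is lexicographic for determinism.  A zero-weight seed yields the
#' degenerate module `{seed}` (filtered later by [find_modules()]).
#'
#' @param network A `coexpression_network`.
#' @param weights Output of [vertex_weights()].
#' @param seed Seed node id.
#' @param config A [module_config()].
#' @param eligible Optional node subset the expansion may use (defaults to
#'   all nodes); used by [find_modules()] to enforce the hard partition.
#' @return Character vector of module node ids (sorted), containing `seed`.
#' @export
expand_module <- function(network, weights, seed, config = module_config(),
                          eligible = network$nodes) {
  w <- setNames(weights$weight, weights$node)
  if (!seed %in% names(w)) stop_rhe("seed not in network", "bad_argument")
  if (w[[seed]] == 0) return(seed)
  adj <- adjacency_sets(network)
  members <- seed
  visited <- seed
  queue <- seed
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- sort(setdiff(intersect(adj[[v]], eligible), visited))
    visited <- c(visited, nb)
    join <- nb[w[nb] / w[[seed]] > config$weight_ratio_min]
    members <- c(members, join)
    queue <- c(queue, join)
  }
  sort(members)
}

#' Mine all modules from a network
#'
#' Iteratively seeds from the highest-weight unassigned node (ties broken by
#' lexicographic id), expands with [expand_module()] among unassigned nodes
#' only, and marks the grown module assigned — a hard partition, matching
#' "deleting the searched node from the network".  Modules are then
#' post-filtered: induced minimum degree at least `min_degree` and node
#' count at least `min_nodes`.
#'
#' @inheritParams expand_module
#' @return List of `module` objects (each: `nodes`, `edges` tibble of the
#'   induced subgraph, `seed`, `score` = mean member weight), sorted by
#'   decreasing size then smallest member id.
#' @export
find_modules <- function(network, config = module_config()) {
  weights <- vertex_weights(network)
  w <- setNames(weights$weight, weights$node)
  unassigned <- network$nodes
  raw <- list()
  while (length(unassigned) > 0L) {
    cand <- unassigned[w[unassigned] == max(w[unassigned])]
    seed <- sort(cand)[1L]
    members <- expand_module(network, weights, seed, config,
                             eligible = unassigned)
    raw[[length(raw) + 1L]] <- list(seed = seed, nodes = members)
    unassigned <- setdiff(unassigned, members)
  }
  mods <- purrr::keep(purrr::map(raw, function(m) {
    e <- induced_edges(network, m$nodes)
    deg <- table(factor(c(e$from, e$to), levels = m$nodes))
    list(nodes = m$nodes, edges = e, seed = m$seed,
         score = mean(w[m$nodes]), min_degree = if (length(m$nodes) == 1L) 0L
         else min(as.integer(deg)))
  }), function(m) {
    length(m$nodes) >= config$min_nodes && m$min_degree >= config$min_degree
  })
  ord <- order(-vapply(mods, function(m) length(m$nodes), integer(1)),
               vapply(mods, function(m) m$nodes[1L], character(1)))
  mods <- mods[ord]
  lapply(mods, function(m) structure(m, class = "rhe_module"))
}

induced_edges <- function(network, nodes) {
  e <- network$edges
  e[e$from %in% nodes & e$to %in% nodes, , drop = FALSE]
}

#' @export
print.rhe_module <- function(x, ...) {
  cat(sprintf("<module> %d nodes, %d edges, seed %s, mean weight %.3f\n",
              length(x$nodes), nrow(x$edges), x$seed, x$score))
  invisible(x)
}

#' @rdname tidy_rhepipe
#' @export
tidy.rhe_module <- function(x, ...) {
  tibble(node = x$nodes, is_seed = x$nodes == x$seed)
}

#' @rdname tidy_rhepipe
#' @export
glance.rhe_module <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         seed = x$seed, score = x$score, min_degree = x$min_degree)
}
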