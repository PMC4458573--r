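#' MA-style abundance plot of a differential-expression table
#'
#' Mean abundance (x, log10 of mean RPKM + 0.01) against the log2 fold
#' change `log2(NRH/RH)` (y); rows passing [filter_de()] are highlighted.
#' Genes detected in only one condition sit on the infinite fold-change
#' rails and are drawn at the plot's y-limits with open triangles.
#'
#' @param tbl Diff table (with `log2fc`).
#' @param criteria A [de_criteria()] used for highlighting.
#' @return A ggplot object.
#' @export
plot_de <- function(tbl, criteria = de_criteria()) {
  de_ids <- filter_de(tbl, criteria)$gene_id
  dat <- dplyr::mutate(
    tbl,
    mean_rpkm = (.data$rpkm_rh + .data$rpkm_nrh) / 2,
    de = .data$gene_id %in% de_ids,
    infinite = is.infinite(.data$log2fc)
  )
  finite <- dat[!dat$infinite & !is.na(dat$log2fc), ]
  ylim <- max(abs(finite$log2fc), 1)
  rails <- dplyr::mutate(dat[dat$infinite, ],
                         log2fc = sign(.data$log2fc) * ylim)
  ggplot2::ggplot(finite, ggplot2::aes(x = log10(.data$mean_rpkm + 0.01),
                                       y = .data$log2fc,
                                       colour = .data$de)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_point(data = rails, shape = 2) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "DE") +
    ggplot2::labs(x = "log10 mean RPKM", y = "log2(NRH / RH)") +
    ggplot2::theme_minimal()
}

#' Plot a co-expression network
#'
#' Fruchterman-Reingold layout (seeded for reproducibility) with edges as
#' segments and nodes coloured by connected component.
#'
#' @param object A `coexpression_network`.
#' @param layout_seed Seed for the layout.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpression_network <- function(object, layout_seed = 1L, ...) {
  g <- igraph::graph_from_data_frame(object$edges[, c("from", "to")],
                                     directed = FALSE)
  xy <- with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- tibble(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  comps <- connected_components(object)
  comp_of <- dplyr::bind_rows(purrr::imap(comps, function(n, i) {
    tibble(node = n, component = factor(i))
  }))
  nodes <- dplyr::left_join(nodes, comp_of, by = "node")
  edges <- dplyr::left_join(
    dplyr::left_join(object$edges, nodes[, c("node", "x", "y")],
                     by = c(from = "node")),
    dplyr::rename(nodes[, c("node", "x", "y")], xend = "x", yend = "y"),
    by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$component), size = 2) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "component")
}

#' Dot plot of enrichment results
#'
#' Terms against -log10 p, classic and (when present) elim side by side;
#' only the `top_n` smallest-p terms are shown.
#'
#' @param results Enrichment tibble.
#' @param top_n Number of terms to display.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, top_n = 15L) {
  key <- if ("p_elim" %in% names(results)) "p_elim" else "p_classic"
  shown <- head(results[order(results[[key]]), ], top_n)
  long <- tidyr::pivot_longer(
    shown, dplyr::any_of(c("p_classic", "p_elim")),
    names_to = "method", values_to = "p")
  long$label <- ifelse(is.na(long$name), long$term_id, long$name)
  ggplot2::ggplot(long, ggplot2::aes(x = -log10(.data$p),
                                     y = stats::reorder(.data$label,
                                                        -.data$p),
                                     colour = .data$method)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "-log10 p", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
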