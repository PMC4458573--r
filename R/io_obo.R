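#' Build a Gene Ontology DAG object
#'
#' The container used by the enrichment machinery: term ids and names, the
#' `is_a` child-to-parent edges, and a gene-to-term annotation table that is
#' closed under ancestor propagation on construction (the true-path rule: a
#' gene annotated to a term is annotated to all its ancestors).
#'
#' @param terms Tibble with columns `term_id`, `name`.
#' @param edges Tibble with columns `child`, `parent` (`is_a` relations).
#' @param annotation Tibble with columns `gene_id`, `term_id` (direct
#'   annotations; propagated automatically).
#' @return An object of class `go_dag`.
#' @export
go_dag <- function(terms, edges, annotation) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  stopifnot(all(c("term_id", "name") %in% names(terms)),
            all(c("child", "parent") %in% names(edges)))
  unknown <- setdiff(c(edges$child, edges$parent), terms$term_id)
  if (length(unknown) > 0L) {
    stop_rhe(sprintf("edge references unknown term: %s", unknown[1L]),
             "bad_ontology")
  }
  parents <- split(edges$parent, factor(edges$child, levels = terms$term_id))
  depths <- dag_depths(terms$term_id, parents)  # errors on cycles
  anc <- dag_ancestors(terms$term_id, parents)
  annotation <- dplyr::distinct(as_tibble(annotation)[, c("gene_id", "term_id")])
  bad_terms <- setdiff(annotation$term_id, terms$term_id)
  if (length(bad_terms) > 0L) {
    stop_rhe(sprintf("annotation references unknown term: %s", bad_terms[1L]),
             "bad_ontology")
  }
  prop <- propagate_annotation(annotation, anc)
  structure(
    list(terms = terms, edges = edges, parents = parents,
         ancestors = anc, depths = depths, annotation = prop),
    class = "go_dag"
  )
}

# Longest-path depth from any root (term with no parents).  Kahn-style
# peeling doubles as the acyclicity check.
dag_depths <- function(ids, parents) {
  depth <- setNames(rep(NA_integer_, length(ids)), ids)
  remaining <- ids
  level <- 0L
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(t) {
      all(!parents[[t]] %in% remaining)
    }, logical(1))]
    if (length(ready) == 0L) {
      stop_rhe("ontology contains a cycle", "cyclic_ontology")
    }
    for (t in ready) {
      p <- parents[[t]]
      depth[[t]] <- if (length(p) == 0L) 0L else max(depth[p]) + 1L
    }
    remaining <- setdiff(remaining, ready)
  }
  depth
}

dag_ancestors <- function(ids, parents) {
  anc <- setNames(vector("list", length(ids)), ids)
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    p <- parents[[t]]
    res <- if (length(p) == 0L) character(0) else {
      unique(c(p, unlist(lapply(p, get_anc), use.names = FALSE)))
    }
    anc[[t]] <<- res
    res
  }
  # depths() already guarantees acyclicity before this is called
  for (t in ids) get_anc(t)
  anc
}

propagate_annotation <- function(annotation, ancestors) {
  extra <- tidyr::unnest(
    dplyr::mutate(annotation, term_id = purrr::map(.data$term_id, function(t) {
      c(t, ancestors[[t]])
    })),
    "term_id"
  )
  dplyr::distinct(dplyr::arrange(extra, .data$gene_id, .data$term_id))
}

#' Read a (subset) OBO ontology file
#'
#' Parses `[Term]` stanzas with `id`, `name` and `is_a` tags.  Relationship
#' tags other than `is_a` are ignored with a warning: the elim enrichment
#' procedure only needs the subsumption hierarchy.  Obsolete terms are
#' skipped.
#'
#' @param path Path to an OBO file.
#' @param annotation Optional tibble (`gene_id`, `term_id`) of direct gene
#'   annotations, e.g. from [read_gene2go()].
#' @return A `go_dag` object (see [go_dag()]).
#' @export
read_obo <- function(path, annotation = tibble(gene_id = character(0),
                                               term_id = character(0))) {
  lines <- readLines(path)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) {
    stop_rhe("no [Term] stanzas found", "bad_ontology")
  }
  bounds <- c(stanza_starts, length(lines) + 1L)
  other_rel <- FALSE
  rows <- purrr::map(seq_along(stanza_starts), function(k) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[!startsWith(chunk, "[")]
    tag_val <- function(tag) {
      hit <- chunk[startsWith(chunk, paste0(tag, ": "))]
      sub(paste0("^", tag, ": "), "", hit)
    }
    if (any(startsWith(chunk, "is_obsolete: true"))) return(NULL)
    rel <- chunk[startsWith(chunk, "relationship: ")]
    if (length(rel) > 0L) other_rel <<- TRUE
    isa <- sub(" !.*$", "", tag_val("is_a"))
    list(id = tag_val("id")[1L],
         name = if (length(tag_val("name")) > 0L) tag_val("name")[1L] else NA_character_,
         parents = isa)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (other_rel) {
    warn("non-is_a relationships present in OBO file; ignored")
  }
  terms <- tibble(
    term_id = vapply(rows, `[[`, character(1), "id"),
    name = vapply(rows, `[[`, character(1), "name")
  )
  edges <- dplyr::bind_rows(purrr::map(rows, function(r) {
    if (length(r$parents) == 0L) return(NULL)
    tibble(child = r$id, parent = r$parents)
  }))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble(child = character(0), parent = character(0))
  }
  go_dag(terms, edges, annotation)
}

#' Write a `go_dag` back to OBO (is_a subset)
#'
#' @param dag A `go_dag` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$term_id[i]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i])), con)
    for (p in dag$parents[[id]]) {
      writeLines(paste0("is_a: ", p), con)
    }
  }
  invisible(path)
}

#' Read / write gene-to-term annotation tables
#'
#' Two-column tab-delimited files (`gene_id`, `term_id`), one direct
#' annotation per line.
#'
#' @param path File path.
#' @return `read_gene2go()`: a tibble with columns `gene_id`, `term_id`.
#' @export
read_gene2go <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)[, c("gene_id", "term_id")]
}

#' @rdname read_gene2go
#' @param annotation Tibble with columns `gene_id`, `term_id`.
#' @export
write_gene2go <- function(annotation, path) {
  write_tsv_dot(annotation[, c("gene_id", "term_id")], path)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d is_a edges, %d propagated annotations\n",
              nrow(x$terms), nrow(x$edges), nrow(x$annotation)))
  invisible(x)
}
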