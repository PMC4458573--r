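#' Configuration for the synthetic-data generators
#'
#' One object drives every generator so a whole pipeline run is reproducible
#' from a single seed (each generator derives its own child seed by a fixed
#' offset).  Defaults emulate the study conditions: a 300-array root
#' compendium, the RHE consensus, planted co-expressed modules of 20 and 9
#' genes at a latent strength whose expected within-module correlation
#' (~0.9) clears the study's 0.83 network cutoff, and DE effects of at
#' least one log2 unit so the two-fold filter rule is decisive.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of genes in the diff table / compendium / ontology
#'   population.
#' @param de_fraction Fraction of genes that are truly differentially
#'   expressed.
#' @param effect_log2_range Range the absolute planted log2 effects are
#'   drawn from (min must be >= 1 so every planted effect clears the
#'   two-fold rule).
#' @param rh_only_count How many DE genes are detected only in root hairs
#'   (NRH abundance exactly 0).
#' @param n_arrays Number of compendium arrays (default 300).
#' @param module_specs List of `c(size, latent_strength)` pairs for planted
#'   co-expression modules.
#' @param noise_sd Standard deviation of the independent noise component.
#' @param genome_len Total synthetic chromosome length in bp.
#' @param n_scan_genes Number of gene models carried by the synthetic
#'   genome.
#' @param n_planted_motifs Named vector: planted consensus instances per
#'   gene in each region class, `c(promoter =, intron =, cds =)`.
#' @param consensus Degenerate IUPAC consensus to plant and scan
#'   (default the RHE).
#' @param dag_terms Number of ontology terms.
#' @param enriched_term_fold Fold over-representation of the planted
#'   enriched term in the study set.
#' @param enriched_term_size Population annotation count of the planted
#'   term.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 1000L,
                         de_fraction = 0.2,
                         effect_log2_range = c(1, 4),
                         rh_only_count = 10L,
                         n_arrays = 300L,
                         module_specs = list(c(size = 20, latent_strength = 0.95),
                                             c(size = 9, latent_strength = 0.95)),
                         noise_sd = 1,
                         genome_len = 30000L,
                         n_scan_genes = 3L,
                         n_planted_motifs = c(promoter = 1L, intron = 1L,
                                              cds = 1L),
                         consensus = "WHHDTGNNN(N)KCACGWH",
                         dag_terms = 50L,
                         enriched_term_fold = 5,
                         enriched_term_size = 40L) {
  assert_scalar_number(de_fraction, "de_fraction", lower = 0, upper = 1)
  assert_scalar_number(rh_only_count, "rh_only_count", lower = 0)
  stopifnot(length(effect_log2_range) == 2L,
            effect_log2_range[1] <= effect_log2_range[2])
  for (m in module_specs) {
    assert_scalar_number(m[["latent_strength"]], "latent_strength",
                         lower = 0, upper = 1)
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         de_fraction = de_fraction, effect_log2_range = effect_log2_range,
         rh_only_count = as.integer(rh_only_count),
         n_arrays = as.integer(n_arrays), module_specs = module_specs,
         noise_sd = noise_sd, genome_len = as.integer(genome_len),
         n_scan_genes = as.integer(n_scan_genes),
         n_planted_motifs = n_planted_motifs, consensus = consensus,
         dag_terms = as.integer(dag_terms),
         enriched_term_fold = enriched_term_fold,
         enriched_term_size = as.integer(enriched_term_size)),
    class = "synth_config"
  )
}

synth_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# Log-normal RPKM baseline spanning the dynamic range seen in real
# root-hair tables (~0.1 to several thousand); DE genes are redrawn until
# their baseline exceeds 1 so the planted truth always clears the
# "RPKM > 1 in either sample" rule.
draw_base_rpkm <- function(n, floor_gt1 = FALSE) {
  x <- rlnorm(n, meanlog = log(3), sdlog = 1.5)
  if (floor_gt1) {
    while (any(x <= 1)) {
      k <- x <= 1
      x[k] <- rlnorm(sum(k), meanlog = log(3), sdlog = 1.5)
    }
  }
  x
}

#' Generate a differential-expression table with planted truth
#'
#' Non-DE genes get near-equal abundances (|log2 ratio| < 1) and
#' q ~ U(0.05, 1); DE genes get |log2 effects| drawn from
#' `effect_log2_range` and q ~ U(0, 0.05); `rh_only_count` of the DE genes
#' are set to NRH abundance exactly 0 with RH abundance > 1.  The filter
#' rules of [filter_de()] therefore recover the planted truth exactly.
#'
#' @param config A [synth_config()].
#' @return List with `table` (a diff tibble incl. `log2fc`) and `truth`
#'   (tibble `gene_id`, `is_de`, `effect_log2`, `rh_only`).
#' @export
gen_diff_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_genes
  de_n <- round_half_away(config$de_fraction * n)
  if (de_n < config$rh_only_count) {
    stop_rhe("de_fraction * n_genes < rh_only_count", "bad_config")
  }
  # Planted co-expression module genes (the leading gene-id block, see
  # gen_compendium) are forced into the RH-up-regulated DE truth so the
  # DE-filter -> network -> module chain of a pipeline run can recover
  # them, mirroring how the study built networks over up-regulated genes.
  module_n <- sum(vapply(config$module_specs, `[[`, numeric(1), "size"))
  if (de_n < module_n + config$rh_only_count) {
    stop_rhe("de_fraction * n_genes too small for module_specs + rh_only_count",
             "bad_config")
  }
  with_seed(child_seed(config$seed, "diff_table"), {
    ids <- synth_gene_ids(n)
    forced <- seq_len(module_n)
    free <- setdiff(seq_len(n), forced)
    de_idx <- sort(c(forced, free[sample.int(length(free), de_n - module_n)]))
    rh_only_pool <- setdiff(de_idx, forced)
    rh_only_idx <- sort(rh_only_pool[sample.int(length(rh_only_pool),
                                                config$rh_only_count)])
    is_de <- seq_len(n) %in% de_idx
    rh_only <- seq_len(n) %in% rh_only_idx

    rpkm_rh <- rpkm_nrh <- numeric(n)
    effect <- numeric(n)

    base_bg <- draw_base_rpkm(n)
    delta_bg <- runif(n, -0.9, 0.9)
    base_de <- draw_base_rpkm(n, floor_gt1 = TRUE)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    sgn[forced] <- -1  # module genes are up in RH (negative log2(NRH/RH))
    eff_abs <- runif(n, config$effect_log2_range[1], config$effect_log2_range[2])

    bg <- !is_de
    rpkm_rh[bg] <- base_bg[bg]
    rpkm_nrh[bg] <- base_bg[bg] * 2^delta_bg[bg]
    effect[bg] <- 0

    de <- is_de & !rh_only
    lfc <- sgn * eff_abs  # log2(nrh/rh) convention
    rpkm_rh[de] <- base_de[de] * 2^pmax(-lfc[de], 0)
    rpkm_nrh[de] <- base_de[de] * 2^pmax(lfc[de], 0)
    effect[de] <- lfc[de]

    rpkm_rh[rh_only] <- base_de[rh_only]
    rpkm_nrh[rh_only] <- 0
    effect[rh_only] <- -Inf

    q <- numeric(n)
    q[bg] <- runif(sum(bg), 0.05, 1)
    q[is_de] <- runif(sum(is_de), 0, 0.05)

    tbl <- tibble(
      gene_id = ids,
      annotation = ifelse(is_de, "synthetic DE gene", "synthetic background gene"),
      rpkm_rh = rpkm_rh, rpkm_nrh = rpkm_nrh,
      q_value = q, status = "OK"
    )
    tbl$log2fc <- log2_fold_change(tbl$rpkm_rh, tbl$rpkm_nrh,
                                   allow_both_zero = TRUE)
    truth <- tibble(gene_id = ids, is_de = is_de, effect_log2 = effect,
                    rh_only = rh_only)
    list(table = tbl, truth = truth)
  })
}

#' Generate a gene-by-array compendium with planted co-expressed modules
#'
#' Module members follow a shared latent factor:
#' `x = s * z + sqrt(1 - s^2) * eps` with `z` a per-array standard-normal
#' latent, `s` the module's latent strength and `eps ~ N(0, noise_sd)`
#' independent noise; background genes are pure noise.  With
#' `noise_sd = 1` the expected within-module correlation is `s^2`.
#' Module gene blocks are assigned from the front of the gene list.
#'
#' @param config A [synth_config()].
#' @return List with `matrix` (genes x arrays) and `truth` (list of module
#'   gene-id sets).
#' @export
gen_compendium <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sizes <- vapply(config$module_specs, `[[`, numeric(1), "size")
  if (sum(sizes) > config$n_genes) {
    stop_rhe("module sizes exceed n_genes", "bad_config")
  }
  with_seed(child_seed(config$seed, "compendium"), {
    ids <- synth_gene_ids(config$n_genes)
    n_arr <- config$n_arrays
    mat <- matrix(rnorm(config$n_genes * n_arr, sd = config$noise_sd),
                  nrow = config$n_genes,
                  dimnames = list(ids, sprintf("Array%03d", seq_len(n_arr))))
    offset <- 0L
    truth <- list()
    for (m in config$module_specs) {
      size <- as.integer(m[["size"]])
      s <- m[["latent_strength"]]
      members <- ids[(offset + 1L):(offset + size)]
      z <- rnorm(n_arr)
      eps <- matrix(rnorm(size * n_arr, sd = config$noise_sd), nrow = size)
      mat[members, ] <- s * matrix(z, nrow = size, ncol = n_arr,
                                   byrow = TRUE) + sqrt(1 - s^2) * eps
      truth[[length(truth) + 1L]] <- members
      offset <- offset + size
    }
    list(matrix = mat, truth = truth)
  })
}

# Draw one concrete instance of a consensus length variant (forward
# orientation text).
sample_consensus_instance <- function(consensus, len) {
  sets <- consensus$variants[[as.character(len)]]
  paste(vapply(sets, function(s) sample(setdiff(s, "N"), 1L), character(1)),
        collapse = "")
}

# Fixed per-gene anatomy of the synthetic genome, in coding orientation.
SYNTH_GENE_LAYOUT <- list(
  margin = 100L, promoter = 3000L,
  exons = c(300L, 300L, 300L), introns = c(400L, 350L), tail = 150L
)

synth_block_len <- function() {
  l <- SYNTH_GENE_LAYOUT
  l$margin + l$promoter + sum(l$exons) + sum(l$introns) + l$tail
}

# Coding-orientation coordinates of the anatomy above.
synth_block_coords <- function() {
  l <- SYNTH_GENE_LAYOUT
  e1s <- l$margin + l$promoter + 1L
  e1e <- e1s + l$exons[1] - 1L
  i1s <- e1e + 1L; i1e <- i1s + l$introns[1] - 1L
  e2s <- i1e + 1L; e2e <- e2s + l$exons[2] - 1L
  i2s <- e2e + 1L; i2e <- i2s + l$introns[2] - 1L
  e3s <- i2e + 1L; e3e <- e3s + l$exons[3] - 1L
  list(
    promoter = c(l$margin + 1L, l$margin + l$promoter),
    exons = rbind(c(e1s, e1e), c(e2s, e2e), c(e3s, e3e)),
    introns = rbind(c(i1s, i1e), c(i2s, i2e)),
    start_codon = e1s
  )
}

# Plant instances into one region string; returns the new string and a
# truth tibble in region-local coordinates.
plant_in_region <- function(region_seq, consensus, n_plant) {
  L_max <- max(consensus$lengths)
  width <- nchar(region_seq)
  truth <- list()
  taken <- integer(0)
  for (k in seq_len(n_plant)) {
    len <- consensus$lengths[sample.int(length(consensus$lengths), 1L)]
    orient <- sample(c("+", "-"), 1L)
    repeat {
      pos <- sample.int(width - L_max + 1L, 1L)
      if (!any(abs(pos - taken) < 2L * L_max)) break
    }
    taken <- c(taken, pos)
    inst <- sample_consensus_instance(consensus, len)
    text <- if (orient == "+") inst else revcomp_chr(inst)
    substr(region_seq, pos, pos + len - 1L) <- text
    truth[[k]] <- tibble(
      start = if (orient == "+") pos else pos + len - 1L,
      end = if (orient == "+") pos + len - 1L else pos,
      orientation = orient, matched_seq = text
    )
  }
  list(seq = region_seq, truth = dplyr::bind_rows(truth))
}

# Build one gene block (coding orientation) with planted motifs; rejection
# sampling regenerates the block until scanning recovers exactly the
# planted truth (no spurious background matches).
build_gene_block <- function(gene_id, consensus, n_plant, max_tries = 200L) {
  co <- synth_block_coords()
  bl <- synth_block_len()
  n_spliced <- sum(SYNTH_GENE_LAYOUT$exons)
  for (try in seq_len(max_tries)) {
    block <- paste(sample(c("A", "C", "G", "T"), bl, replace = TRUE),
                   collapse = "")
    truth <- list()
    # promoter
    prom <- substr(block, co$promoter[1], co$promoter[2])
    pl <- plant_in_region(prom, consensus, n_plant[["promoter"]])
    substr(block, co$promoter[1], co$promoter[2]) <- pl$seq
    if (nrow(pl$truth) > 0L) {
      truth[[length(truth) + 1L]] <- dplyr::mutate(pl$truth,
                                                   region = "promoter",
                                                   region_index = 0L)
    }
    # one randomly chosen intron
    if (n_plant[["intron"]] > 0L) {
      iidx <- sample.int(nrow(co$introns), 1L)
      intr <- substr(block, co$introns[iidx, 1], co$introns[iidx, 2])
      pl <- plant_in_region(intr, consensus, n_plant[["intron"]])
      substr(block, co$introns[iidx, 1], co$introns[iidx, 2]) <- pl$seq
      truth[[length(truth) + 1L]] <- dplyr::mutate(pl$truth,
                                                   region = "intron",
                                                   region_index = iidx)
    }
    # spliced CDS: plant inside a single exon segment so the instance is
    # contiguous both in genomic and spliced space
    if (n_plant[["cds"]] > 0L) {
      L_max <- max(consensus$lengths)
      eidx <- sample.int(nrow(co$exons), 1L)
      ex <- substr(block, co$exons[eidx, 1], co$exons[eidx, 2])
      pl <- plant_in_region(ex, consensus, n_plant[["cds"]])
      substr(block, co$exons[eidx, 1], co$exons[eidx, 2]) <- pl$seq
      spliced_off <- if (eidx == 1L) 0L else
        sum(SYNTH_GENE_LAYOUT$exons[seq_len(eidx - 1L)])
      truth[[length(truth) + 1L]] <- dplyr::mutate(
        pl$truth, start = .data$start + spliced_off,
        end = .data$end + spliced_off, region = "cds", region_index = 0L)
    }
    truth <- dplyr::bind_rows(truth)
    if (nrow(truth) == 0L) {
      truth <- tibble(start = integer(0), end = integer(0),
                      orientation = character(0), matched_seq = character(0),
                      region = character(0), region_index = integer(0))
    }
    truth$gene_id <- rep(gene_id, nrow(truth))
    # verify by scanning the block's regions directly (coding orientation)
    ok <- verify_block(block, co, consensus, truth)
    if (ok) return(list(block = block, truth = truth))
  }
  stop_rhe("failed to generate a motif-clean gene block", "generator_failure")
}

verify_block <- function(block, co, consensus, truth) {
  regions <- list(
    list(region = "promoter", region_index = 0L,
         seq = substr(block, co$promoter[1], co$promoter[2])),
    list(region = "intron", region_index = 1L,
         seq = substr(block, co$introns[1, 1], co$introns[1, 2])),
    list(region = "intron", region_index = 2L,
         seq = substr(block, co$introns[2, 1], co$introns[2, 2])),
    list(region = "cds", region_index = 0L,
         seq = paste(vapply(seq_len(nrow(co$exons)), function(i) {
           substr(block, co$exons[i, 1], co$exons[i, 2])
         }, character(1)), collapse = ""))
  )
  found <- dplyr::bind_rows(purrr::map(regions, function(r) {
    h <- scan_region(r$seq, consensus)
    if (nrow(h) == 0L) return(NULL)
    dplyr::mutate(h[, c("start", "end", "orientation", "matched_seq")],
                  region = r$region, region_index = r$region_index)
  }))
  key <- function(d) {
    if (nrow(d) == 0L) return(character(0))
    sort(paste(d$region, d$region_index, d$start, d$end, d$orientation,
               d$matched_seq))
  }
  identical(key(found), key(truth))
}

#' Generate a synthetic genome with planted consensus instances
#'
#' Builds `n_scan_genes` three-exon gene models (alternating strands) on one
#' random chromosome, each with a 3000 bp promoter clearance, and plants
#' `n_planted_motifs` concrete instances of the consensus per region class
#' at recorded positions and orientations.  Rejection sampling guarantees
#' that scanning each gene recovers exactly the planted truth (no spurious
#' background hits).
#'
#' @param config A [synth_config()].
#' @return List with `genome` (named character vector), `models`
#'   (gene-model tibble), `truth` (hit tibble in region-local coordinates,
#'   reverse hits with `start > end`), and `consensus` (parsed).
#' @export
gen_genome_with_motifs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  consensus <- parse_consensus(config$consensus)
  bl <- synth_block_len()
  needed <- config$n_scan_genes * bl
  if (config$genome_len < needed) {
    stop_rhe(sprintf("genome_len %d too short for %d genes (need %d)",
                     config$genome_len, config$n_scan_genes, needed),
             "bad_config")
  }
  with_seed(child_seed(config$seed, "genome"), {
    co <- synth_block_coords()
    ids <- synth_gene_ids(config$n_scan_genes)
    blocks <- character(config$n_scan_genes)
    models <- list()
    truths <- list()
    for (i in seq_len(config$n_scan_genes)) {
      strand <- if (i %% 2L == 1L) "+" else "-"
      gb <- build_gene_block(ids[i], consensus, config$n_planted_motifs)
      off <- (i - 1L) * bl
      if (strand == "+") {
        blocks[i] <- gb$block
        g <- function(p) off + p
        exons <- cbind(g(co$exons[, 1]), g(co$exons[, 2]))
      } else {
        blocks[i] <- revcomp_chr(gb$block)
        g <- function(p) off + bl - p + 1L
        exons <- cbind(g(co$exons[, 2]), g(co$exons[, 1]))
      }
      models[[i]] <- gene_model(
        gene_id = ids[i], transcript_id = paste0(ids[i], ".1"),
        chrom = "Chr1", strand = strand,
        exons = exons, cds = exons
      )
      truths[[i]] <- gb$truth
    }
    tail_len <- config$genome_len - needed
    tail_seq <- if (tail_len > 0L) {
      paste(sample(c("A", "C", "G", "T"), tail_len, replace = TRUE),
            collapse = "")
    } else ""
    genome <- c(Chr1 = paste0(paste(blocks, collapse = ""), tail_seq))
    truth <- dplyr::bind_rows(truths)
    truth <- truth[, c("gene_id", "region", "region_index", "start", "end",
                       "orientation", "matched_seq")]
    list(genome = genome, models = dplyr::bind_rows(models),
         truth = truth, consensus = consensus)
  })
}

#' Generate a random ontology DAG with a planted enriched term
#'
#' Terms beyond the root receive one or two parents among earlier
#' (shallower) terms; each non-root term gets a random direct annotation
#' which is propagated to ancestors on construction.  One designated term's
#' annotation overlaps `study_genes` `enriched_term_fold`-fold above the
#' hypergeometric expectation.
#'
#' @param config A [synth_config()].
#' @param study_genes Character vector of study gene ids (subset of the
#'   generated population).
#' @return List with `dag` (a `go_dag`), `population` (gene ids) and
#'   `truth` (list with `enriched_term`, `x_planted`).
#' @export
gen_go <- function(config, study_genes) {
  stopifnot(inherits(config, "synth_config"))
  population <- synth_gene_ids(config$n_genes)
  if (!all(study_genes %in% population)) {
    stop_rhe("study_genes must be drawn from the generated population",
             "bad_config")
  }
  nt <- config$dag_terms
  with_seed(child_seed(config$seed, "ontology"), {
    term_ids <- sprintf("T%03d", seq_len(nt))
    terms <- tibble(term_id = term_ids,
                    name = paste("synthetic process", seq_len(nt)))
    edges <- if (nt > 1L) {
      dplyr::bind_rows(purrr::map(2:nt, function(i) {
        k <- sample(1:2, 1L)
        tibble(child = term_ids[i],
               parent = term_ids[sample.int(i - 1L, min(k, i - 1L))])
      }))
    } else tibble(child = character(0), parent = character(0))

    if (nt == 1L) {
      ann <- tibble(gene_id = population, term_id = term_ids[1L])
      dag <- go_dag(terms, edges, ann)
      return(list(dag = dag, population = population,
                  truth = list(enriched_term = NA_character_,
                               x_planted = NA_integer_)))
    }

    M <- length(study_genes)
    N <- length(population)
    K <- min(config$enriched_term_size, N)
    x <- round_half_away(config$enriched_term_fold * K * M / N)
    if (x > min(K, M)) {
      stop_rhe("enriched term impossible at requested fold", "bad_config")
    }
    enriched <- term_ids[nt]

    ann <- purrr::map(setdiff(2:nt, nt), function(i) {
      size <- sample(5:40, 1L)
      tibble(gene_id = sample(population, size), term_id = term_ids[i])
    })
    non_study <- setdiff(population, study_genes)
    ann[[length(ann) + 1L]] <- tibble(
      gene_id = c(sample(study_genes, x), sample(non_study, K - x)),
      term_id = enriched
    )
    dag <- go_dag(terms, edges, dplyr::bind_rows(ann))
    list(dag = dag, population = population,
         truth = list(enriched_term = enriched, x_planted = x))
  })
}
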