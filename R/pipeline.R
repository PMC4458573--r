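#' Pipeline configuration
#'
#' Bundles every stage's settings plus the file layout of one run.  The six
#' stages mirror the study's analysis order: `simulate` (synthetic inputs
#' with planted truth), `de-filter`, `scan-rhe`, `coexpress` (optionally
#' with a threshold sweep), `modules`, `enrich`.  When `simulate` is
#' dropped, the corresponding input files must already exist in `out_dir`
#' (or be supplied via `inputs`).
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; fans out to per-stage child seeds.
#' @param stages Character vector of stages to run, executed in canonical
#'   order regardless of the order given.
#' @param synth A [synth_config()] (its `seed` is overridden by `seed`).
#' @param criteria A [de_criteria()].
#' @param region A [region_spec()].
#' @param threshold Correlation cutoff used when `sweep = FALSE`.
#' @param sweep If `TRUE`, choose the threshold with [select_threshold()]
#'   over `grid` instead of using `threshold` directly.
#' @param grid Sweep grid.
#' @param module_cfg A [module_config()].
#' @param elim_cfg An [elim_config()].
#' @param inputs Named list of pre-existing input paths overriding the
#'   defaults under `out_dir` (names among `diff_table`, `compendium`,
#'   `genome`, `gff3`, `obo`, `gene2go`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = c("simulate", "de-filter", "scan-rhe",
                                       "coexpress", "modules", "enrich"),
                            synth = synth_config(seed = seed),
                            criteria = de_criteria(),
                            region = region_spec(),
                            threshold = 0.83,
                            sweep = FALSE,
                            grid = seq(0.70, 0.90, by = 0.01),
                            module_cfg = module_config(),
                            elim_cfg = elim_config(),
                            inputs = list()) {
  all_stages <- c("simulate", "de-filter", "scan-rhe", "coexpress",
                  "modules", "enrich")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) {
    stop_rhe(sprintf("unknown stage '%s'", bad[1L]), "bad_config")
  }
  synth$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         stages = all_stages[all_stages %in% stages],
         synth = synth, criteria = criteria, region = region,
         threshold = threshold, sweep = sweep, grid = grid,
         module_cfg = module_cfg, elim_cfg = elim_cfg, inputs = inputs),
    class = "pipeline_config"
  )
}

pipeline_path <- function(config, name) {
  defaults <- c(
    diff_table = "diff_table.tsv", compendium = "compendium.tsv",
    genome = "genome.fa", gff3 = "models.gff3", obo = "ontology.obo",
    gene2go = "gene2go.tsv"
  )
  config$inputs[[name]] %||% file.path(config$out_dir, defaults[[name]])
}

validate_pipeline <- function(config) {
  if (!"simulate" %in% config$stages) {
    need <- c(
      `de-filter` = "diff_table", `scan-rhe` = "gff3",
      coexpress = "compendium", enrich = "obo"
    )
    for (stage in intersect(names(need), config$stages)) {
      p <- pipeline_path(config, need[[stage]])
      if (!file.exists(p)) {
        stop_rhe(sprintf("stage '%s' needs missing input file: %s", stage, p),
                 "missing_input")
      }
    }
    if ("scan-rhe" %in% config$stages &&
        !file.exists(pipeline_path(config, "genome"))) {
      stop_rhe(sprintf("stage 'scan-rhe' needs missing input file: %s",
                       pipeline_path(config, "genome")), "missing_input")
    }
  }
  invisible(config)
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order, writing each stage's outputs
#' under `out_dir` and finally a manifest (`manifest.tsv`) listing every
#' artifact with its MD5 content hash and record count.  Runs with the same
#' seed produce byte-identical artifacts and manifests.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log messages.
#' @return The manifest tibble (`stage`, `file`, `md5`, `n_records`),
#'   invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[rhepipe] ", fmt), ...))
  }
  add <- function(stage, path, n_records) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), n_records = n_records
    )
  }

  for (stage in config$stages) {
    t0 <- Sys.time()
    switch(stage,
      "simulate" = {
        sim <- gen_diff_table(config$synth)
        write_diff_table(sim$table, pipeline_path(config, "diff_table"))
        add(stage, pipeline_path(config, "diff_table"), nrow(sim$table))
        truth_path <- file.path(config$out_dir, "truth_de.tsv")
        write_tsv_dot(sim$truth, truth_path)
        add(stage, truth_path, nrow(sim$truth))

        comp <- gen_compendium(config$synth)
        write_compendium(comp$matrix, pipeline_path(config, "compendium"))
        add(stage, pipeline_path(config, "compendium"), nrow(comp$matrix))
        mod_truth <- dplyr::bind_rows(purrr::imap(comp$truth, function(g, i) {
          tibble(module = i, gene_id = g)
        }))
        write_tsv_dot(mod_truth, file.path(config$out_dir, "truth_modules.tsv"))
        add(stage, file.path(config$out_dir, "truth_modules.tsv"),
            nrow(mod_truth))

        gen <- gen_genome_with_motifs(config$synth)
        write_fasta(gen$genome, pipeline_path(config, "genome"))
        add(stage, pipeline_path(config, "genome"), length(gen$genome))
        write_gff3(gen$models, pipeline_path(config, "gff3"))
        add(stage, pipeline_path(config, "gff3"), nrow(gen$models))
        write_hits(gen$truth, file.path(config$out_dir, "truth_hits.tsv"))
        add(stage, file.path(config$out_dir, "truth_hits.tsv"),
            nrow(gen$truth))

        study <- sim$truth$gene_id[sim$truth$is_de]
        go <- gen_go(config$synth, study)
        write_obo(go$dag, pipeline_path(config, "obo"))
        add(stage, pipeline_path(config, "obo"), nrow(go$dag$terms))
        direct <- go$dag$annotation
        write_gene2go(direct, pipeline_path(config, "gene2go"))
        add(stage, pipeline_path(config, "gene2go"), nrow(direct))
      },
      "de-filter" = {
        tbl <- read_diff_table(pipeline_path(config, "diff_table"))
        de <- filter_de(tbl, config$criteria)
        de_path <- file.path(config$out_dir, "de_genes.tsv")
        write_tsv_dot(de[, c("gene_id", "log2fc", "q_value", "direction")],
                      de_path)
        add(stage, de_path, nrow(de))
        rh_path <- file.path(config$out_dir, "rh_only.tsv")
        write_gene_set(rh_only_genes(tbl), rh_path)
        add(stage, rh_path, length(rh_only_genes(tbl)))
      },
      "scan-rhe" = {
        genome <- read_fasta(pipeline_path(config, "genome"))
        models <- read_gff3(pipeline_path(config, "gff3"))
        consensus <- parse_consensus(config$synth$consensus)
        hits <- scan_gene(models, genome, consensus, config$region)
        hits_path <- file.path(config$out_dir, "hits.tsv")
        write_hits(hits, hits_path)
        add(stage, hits_path, nrow(hits))
        bed_path <- file.path(config$out_dir, "hits.bed")
        write_hits_bed(hits, bed_path)
        add(stage, bed_path, nrow(hits))
      },
      "coexpress" = {
        mat <- read_compendium(pipeline_path(config, "compendium"))
        genes <- coexpress_input_genes(config, mat)
        th <- config$threshold
        if (config$sweep) {
          dag <- load_pipeline_dag(config)
          sw <- select_threshold(mat, genes, dag, grid = config$grid)
          th <- sw$chosen
          sweep_path <- file.path(config$out_dir, "threshold_sweep.tsv")
          write_tsv_dot(sw$sweep, sweep_path)
          add(stage, sweep_path, nrow(sw$sweep))
        }
        net <- build_network(mat, genes, threshold = th)
        edges_path <- file.path(config$out_dir, "network_edges.tsv")
        nodes_path <- file.path(config$out_dir, "network_nodes.tsv")
        write_network(net, edges_path, nodes_path)
        add(stage, edges_path, nrow(net$edges))
        add(stage, nodes_path, length(net$nodes))
        comps <- connected_components(net)
        comp_tbl <- dplyr::bind_rows(purrr::imap(comps, function(g, i) {
          tibble(component = i, node = g)
        }))
        if (nrow(comp_tbl) == 0L) {
          comp_tbl <- tibble(component = integer(0), node = character(0))
        }
        comp_path <- file.path(config$out_dir, "components.tsv")
        write_tsv_dot(comp_tbl, comp_path)
        add(stage, comp_path, length(comps))
      },
      "modules" = {
        net <- read_network(file.path(config$out_dir, "network_edges.tsv"))
        mods <- find_modules(net, config$module_cfg)
        mod_tbl <- dplyr::bind_rows(purrr::imap(mods, function(m, i) {
          tibble(module = i, node = m$nodes, seed = m$seed,
                 score = m$score)
        }))
        if (nrow(mod_tbl) == 0L) {
          mod_tbl <- tibble(module = integer(0), node = character(0),
                            seed = character(0), score = numeric(0))
        }
        mod_path <- file.path(config$out_dir, "modules.tsv")
        write_tsv_dot(mod_tbl, mod_path)
        add(stage, mod_path, length(mods))
      },
      "enrich" = {
        dag <- load_pipeline_dag(config)
        study <- enrich_study_genes(config)
        population <- dag_population(config, dag)
        res <- elim_enrichment(dag, study, population, config$elim_cfg)
        enr_path <- file.path(config$out_dir, "enrichment.tsv")
        write_enrichment(res, enr_path)
        add(stage, enr_path, nrow(res))
      }
    )
    say("stage %-9s done in %.2fs", stage,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  out <- dplyr::bind_rows(manifest)
  write_tsv_dot(out, file.path(config$out_dir, "manifest.tsv"))
  say("wrote %d artifacts to %s", nrow(out), config$out_dir)
  invisible(out)
}

# Genes fed to the co-expression stage: the RH-up-regulated DE genes when a
# de-filter output exists, otherwise every compendium gene.
coexpress_input_genes <- function(config, mat) {
  de_path <- file.path(config$out_dir, "de_genes.tsv")
  if (file.exists(de_path)) {
    de <- readr::read_tsv(de_path, col_types = readr::cols(.default = "c"),
                          na = ".", progress = FALSE)
    genes <- intersect(de$gene_id[de$direction == "up_in_rh"], rownames(mat))
    if (length(genes) >= 2L) return(genes)
  }
  rownames(mat)
}

load_pipeline_dag <- function(config) {
  read_obo(pipeline_path(config, "obo"),
           annotation = read_gene2go(pipeline_path(config, "gene2go")))
}

enrich_study_genes <- function(config) {
  nodes_path <- file.path(config$out_dir, "network_nodes.tsv")
  de_path <- file.path(config$out_dir, "de_genes.tsv")
  if (file.exists(nodes_path)) {
    nodes <- readr::read_tsv(nodes_path, col_types = readr::cols(.default = "c"),
                             na = ".", progress = FALSE)
    if (nrow(nodes) > 0L) return(nodes$node)
  }
  if (file.exists(de_path)) {
    de <- readr::read_tsv(de_path, col_types = readr::cols(.default = "c"),
                          na = ".", progress = FALSE)
    if (nrow(de) > 0L) return(de$gene_id)
  }
  stop_rhe("stage 'enrich' found neither a network nor a DE gene list",
           "missing_input")
}

dag_population <- function(config, dag) {
  diff_path <- pipeline_path(config, "diff_table")
  if (file.exists(diff_path)) {
    read_diff_table(diff_path)$gene_id
  } else {
    unique(dag$annotation$gene_id)
  }
}
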