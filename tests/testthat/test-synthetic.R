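test_that("diff-table generator enforces counts and is deterministic", {
  cfg <- synth_config(seed = 1, n_genes = 1000, de_fraction = 0.2,
                      rh_only_count = 5)
  sim <- gen_diff_table(cfg)
  expect_equal(sum(sim$truth$is_de), 200L)
  expect_equal(sum(sim$table$rpkm_nrh == 0), 5L)
  expect_equal(sum(sim$truth$rh_only), 5L)
  # rh-only rows: NRH exactly 0, RH above the filter floor
  rh_only <- sim$table[sim$table$gene_id %in%
                         sim$truth$gene_id[sim$truth$rh_only], ]
  expect_true(all(rh_only$rpkm_nrh == 0))
  expect_true(all(rh_only$rpkm_rh > 1))

  sim2 <- gen_diff_table(cfg)
  expect_identical(sim, sim2)

  # planted labels drive the q-values and effects
  de_rows <- sim$table[sim$truth$is_de, ]
  bg_rows <- sim$table[!sim$truth$is_de, ]
  expect_true(all(de_rows$q_value < 0.05))
  expect_true(all(bg_rows$q_value >= 0.05))
  expect_true(all(abs(bg_rows$log2fc) < 1))
  expect_true(all(abs(de_rows$log2fc) >= 1))

  expect_error(gen_diff_table(synth_config(n_genes = 100, de_fraction = 0.1,
                                           rh_only_count = 50)),
               class = "rhepipe_bad_config")
})

test_that("compendium generator hits its degenerate correlation limits", {
  base <- synth_config(seed = 3, n_genes = 60, n_arrays = 40)
  perfect <- base
  perfect$module_specs <- list(c(size = 5, latent_strength = 1))
  m1 <- gen_compendium(perfect)
  cm <- cor(t(m1$matrix[m1$truth[[1]], ]))
  expect_true(all(abs(cm - 1) < 1e-12))

  null <- base
  null$n_arrays <- 200L
  null$module_specs <- list(c(size = 10, latent_strength = 0))
  m0 <- gen_compendium(null)
  cm0 <- cor(t(m0$matrix[m0$truth[[1]], ]))
  off <- cm0[upper.tri(cm0)]
  expect_true(mean(abs(off)) < 3 / sqrt(200))

  over <- base
  over$module_specs <- list(c(size = 100, latent_strength = 0.5))
  expect_error(gen_compendium(over), class = "rhepipe_bad_config")
})

test_that("strong planted modules exceed the network threshold on average", {
  cfg <- synth_config(seed = 5, n_genes = 60, n_arrays = 300,
                      module_specs = list(c(size = 20, latent_strength = 0.95),
                                          c(size = 9, latent_strength = 0.95)))
  comp <- gen_compendium(cfg)
  for (members in comp$truth) {
    cm <- cor(t(comp$matrix[members, ]))
    expect_gt(mean(cm[upper.tri(cm)]), 0.83)
  }
})

test_that("genome generator plants recoverable motifs on both strands", {
  cfg <- synth_config(seed = 9, n_scan_genes = 4, genome_len = 20000)
  gen <- gen_genome_with_motifs(cfg)
  expect_equal(nrow(gen$truth), 4L * 3L)
  expect_setequal(unique(gen$truth$region), c("promoter", "intron", "cds"))

  # every planted instance matches the consensus in its stated orientation
  for (i in seq_len(nrow(gen$truth))) {
    h <- gen$truth[i, ]
    expect_true(match_at(h$matched_seq, 1, gen$consensus,
                         length = nchar(h$matched_seq),
                         orientation = h$orientation))
  }
  # reverse-orientation truth stores the region-strand text whose reverse
  # complement (by an independent routine) matches forward
  rev_hits <- gen$truth[gen$truth$orientation == "-", ]
  expect_gt(nrow(rev_hits), 0L)
  for (s in rev_hits$matched_seq) {
    expect_true(match_at(oracle_revcomp(s), 1, gen$consensus,
                         length = nchar(s)))
  }
  # determinism
  gen2 <- gen_genome_with_motifs(cfg)
  expect_identical(gen$genome, gen2$genome)
  expect_identical(gen$truth, gen2$truth)

  expect_error(gen_genome_with_motifs(synth_config(genome_len = 1000)),
               class = "rhepipe_bad_config")
})

test_that("ontology generator plants a detectable enriched term", {
  cfg <- synth_config(seed = 13, n_genes = 1000, dag_terms = 50,
                      enriched_term_fold = 5, enriched_term_size = 40)
  study <- synth_gene_ids_for_test(1000)[1:50]
  go <- gen_go(cfg, study)
  expect_false(is.na(go$truth$enriched_term))

  # propagation closure: every annotated child term implies its ancestors
  ann <- go$dag$annotation
  for (i in sample.int(nrow(ann), 50)) {
    anc <- go$dag$ancestors[[ann$term_id[i]]]
    if (length(anc) > 0) {
      mine <- ann$term_id[ann$gene_id == ann$gene_id[i]]
      expect_true(all(anc %in% mine))
    }
  }

  # planted term beats the exhaustive hypergeometric threshold
  sets <- split(ann$gene_id, ann$term_id)
  planted <- sets[[go$truth$enriched_term]]
  x <- length(intersect(planted, study))
  p <- oracle_hyper_upper(x, 50, length(planted), 1000)
  expect_lt(p, 0.01)

  # single-term ontology: the root annotates everything, enrichment is moot
  tiny <- synth_config(seed = 13, n_genes = 20, dag_terms = 1)
  go1 <- gen_go(tiny, synth_gene_ids_for_test(20)[1:5])
  expect_equal(nrow(go1$dag$terms), 1L)
  res <- classic_enrichment(go1$dag, synth_gene_ids_for_test(20)[1:5],
                            go1$population)
  expect_equal(res$p_classic, 1)

  expect_error(gen_go(synth_config(n_genes = 100, enriched_term_fold = 50),
                      synth_gene_ids_for_test(100)[1:50]),
               class = "rhepipe_bad_config")
})
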