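test_that("RPKM arithmetic matches the closed form", {
  expect_equal(compute_rpkm(0, 1000, 1e7), 0)
  expect_equal(compute_rpkm(1000, 2000, 1e7), 50)
  # scale symmetry: doubling count and library size cancels
  expect_equal(compute_rpkm(2000, 2000, 2e7), compute_rpkm(1000, 2000, 1e7))
  expect_error(compute_rpkm(10, 0, 1e7), class = "rhepipe_bad_argument")
  expect_error(compute_rpkm(10, 1000, 0), class = "rhepipe_bad_argument")
})

test_that("log2 fold change follows the NRH/RH sign and infinity rules", {
  # published pair: strongly RH-enriched extensin-like gene
  expect_equal(log2_fold_change(282.55, 0.145177), -10.9265,
               tolerance = 1e-3)
  expect_equal(log2_fold_change(0, 1.08437), Inf)
  expect_equal(log2_fold_change(1.08437, 0), -Inf)
  expect_equal(log2_fold_change(7.5, 7.5), 0)
  expect_error(log2_fold_change(0, 0), class = "rhepipe_bad_argument")
  expect_error(log2_fold_change(-1, 2), class = "rhepipe_bad_argument")

  # antisymmetry property on random positive pairs
  withr::local_seed(21)
  a <- runif(200, 0.01, 1000)
  b <- runif(200, 0.01, 1000)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
})

test_that("DE filter equals the three-predicate oracle on random records", {
  withr::local_seed(31)
  n <- 1000
  tbl <- tibble::tibble(
    gene_id = sprintf("r%04d", 1:n),
    annotation = NA_character_,
    rpkm_rh = ifelse(runif(n) < 0.05, 0, exp(runif(n, -3, 6))),
    rpkm_nrh = ifelse(runif(n) < 0.05, 0, exp(runif(n, -3, 6))),
    q_value = runif(n),
    status = sample(c("OK", "NOTEST"), n, TRUE, prob = c(0.9, 0.1))
  )
  # avoid the undefined both-zero case
  both0 <- tbl$rpkm_rh == 0 & tbl$rpkm_nrh == 0
  tbl$rpkm_rh[both0] <- 1
  tbl$log2fc <- log2_fold_change(tbl$rpkm_rh, tbl$rpkm_nrh)

  got <- filter_de(tbl)
  want <- tbl$gene_id[mapply(oracle_de_pass, tbl$rpkm_rh, tbl$rpkm_nrh,
                             tbl$q_value, tbl$status)]
  expect_setequal(got$gene_id, want)

  # partition: directions are disjoint and exhaustive
  parts <- de_partition(got)
  expect_length(intersect(parts$up_in_rh, parts$up_in_nrh), 0)
  expect_setequal(c(parts$up_in_rh, parts$up_in_nrh), got$gene_id)

  # idempotence and order-independence
  again <- filter_de(got)
  expect_setequal(again$gene_id, got$gene_id)
  shuffled <- filter_de(tbl[sample.int(n), ])
  expect_setequal(shuffled$gene_id, got$gene_id)
})

test_that("DE filter boundaries are strict", {
  row <- function(q, rh, nrh) tibble::tibble(
    gene_id = "g", annotation = NA, rpkm_rh = rh, rpkm_nrh = nrh,
    q_value = q, status = "OK",
    log2fc = log2_fold_change(rh, nrh, allow_both_zero = TRUE))
  expect_equal(nrow(filter_de(row(0.05, 10, 1))), 0L)     # q not < 0.05
  expect_equal(nrow(filter_de(row(0.01, 10, 5))), 0L)     # exactly 2-fold
  expect_equal(nrow(filter_de(row(0.001, 0.9, 0.4))), 0L) # neither RPKM > 1
  pass <- filter_de(row(0.01, 10, 1))
  expect_equal(pass$direction, "up_in_rh")
})

test_that("DE filter recovers the planted truth exactly", {
  sim <- gen_diff_table(synth_config(seed = 4, n_genes = 2000,
                                     de_fraction = 0.15, rh_only_count = 8))
  de <- filter_de(sim$table)
  expect_setequal(de$gene_id, sim$truth$gene_id[sim$truth$is_de])
  parts <- de_partition(de)
  up_rh_truth <- sim$truth$gene_id[sim$truth$is_de & sim$truth$effect_log2 < 0]
  expect_setequal(parts$up_in_rh, up_rh_truth)
  expect_setequal(rh_only_genes(sim$table),
                  sim$truth$gene_id[sim$truth$rh_only])
  # near-zero but nonzero NRH abundance is not "RH only"
  tweaked <- sim$table
  tweaked$rpkm_nrh[tweaked$rpkm_nrh == 0] <- 1e-9
  expect_length(rh_only_genes(tweaked), 0)
})

test_that("overlap statistics reproduce the published percentages", {
  a <- sprintf("p%04d", 1:635)
  b <- c(a[1:580], sprintf("q%04d", 1:500))
  st <- overlap_stats(a, b)
  expect_equal(st$n_overlap, 580L)
  expect_equal(st$pct_of_a, 91)

  st2 <- overlap_stats(sprintf("x%04d", 1:2172), sprintf("x%04d", 1:264))
  expect_equal(st2$pct_of_a, 12)

  same <- overlap_stats(a, a)
  expect_equal(c(same$pct_of_a, same$pct_of_b), c(100, 100))
  expect_equal(overlap_stats(a, paste0("z", 1:10))$n_overlap, 0L)
  expect_true(is.na(overlap_stats(character(0), a)$pct_of_a))
})

test_that("novel-locus flagging matches brute-force interval overlap", {
  mk <- function(id, chrom, s, e) gene_model(id, paste0(id, ".1"), chrom, "+",
                                             exons = rbind(c(s, e)))
  ref <- dplyr::bind_rows(mk("r1", "c1", 1000L, 2000L),
                          mk("r2", "c2", 500L, 900L))
  merged <- dplyr::bind_rows(
    mk("inside", "c1", 1200L, 1400L),
    mk("edge1bp", "c1", 2000L, 2500L),   # 1 bp overlap -> not novel
    mk("clear", "c1", 2001L, 2500L),     # adjacent, no overlap -> novel
    mk("otherchrom", "c3", 100L, 200L)   # chromosome absent -> novel
  )
  expect_setequal(flag_novel_loci(merged, ref), c("clear", "otherchrom"))

  # randomized agreement with a literal pairwise check
  withr::local_seed(41)
  for (rep in 1:10) {
    rs <- sample.int(5000, 6)
    ref_r <- dplyr::bind_rows(lapply(1:3, function(i)
      mk(paste0("R", i), "cc", rs[i], rs[i] + sample.int(400, 1))))
    ms <- sample.int(5000, 4)
    mer_r <- dplyr::bind_rows(lapply(1:4, function(i)
      mk(paste0("M", i), "cc", ms[i], ms[i] + sample.int(400, 1))))
    got <- flag_novel_loci(mer_r, ref_r)
    for (i in 1:4) {
      m <- mer_r[i, ]
      ov <- any(vapply(1:3, function(j) {
        r <- ref_r[j, ]
        max(m$exons[[1]][1], r$exons[[1]][1]) <=
          min(m$exons[[1]][2], r$exons[[1]][2])
      }, logical(1)))
      expect_equal(m$gene_id %in% got, !ov)
    }
  }
})

test_that("expression-pattern clustering recovers planted modules", {
  cfg <- synth_config(seed = 6, n_genes = 50, n_arrays = 200,
                      module_specs = list(c(size = 12, latent_strength = 0.95),
                                          c(size = 8, latent_strength = 0.95)))
  comp <- gen_compendium(cfg)
  genes <- c(comp$truth[[1]], comp$truth[[2]])
  cl <- cluster_expression_patterns(genes, comp$matrix, k = 2)
  split1 <- cl$gene_id[cl$cluster == cl$cluster[cl$gene_id == genes[1]]]
  expect_setequal(split1, comp$truth[[1]])

  # k = |genes| gives singletons
  single <- cluster_expression_patterns(genes[1:5], comp$matrix, k = 5)
  expect_equal(sort(table(single$cluster)), sort(table(1:5)),
               ignore_attr = TRUE)

  # duplicated profiles co-cluster
  mat <- comp$matrix
  mat["G00030", ] <- mat["G00001", ]
  cl2 <- cluster_expression_patterns(c("G00001", "G00030", comp$truth[[2]]),
                                     mat, k = 2)
  expect_equal(cl2$cluster[cl2$gene_id == "G00001"],
               cl2$cluster[cl2$gene_id == "G00030"])

  # constant gene dropped with a warning
  mat["G00040", ] <- 5
  expect_warning(
    cl3 <- cluster_expression_patterns(c(comp$truth[[1]], "G00040"), mat, 2),
    "constant")
  expect_false("G00040" %in% cl3$gene_id)
})
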