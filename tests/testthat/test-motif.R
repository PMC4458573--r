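test_that("consensus parsing expands the optional base", {
  cons <- parse_consensus(RHE_RAW)
  expect_equal(cons$lengths, c(16L, 17L))
  expect_equal(cons$code_map$W, c("A", "T"))
  expect_equal(cons$code_map$D, c("A", "G", "T"))

  lit <- parse_consensus("ACGT")
  expect_equal(lit$lengths, 4L)
  expect_true(match_at("ACGT", 1, lit, 4))
  expect_false(match_at("ACGA", 1, lit, 4))

  expect_error(parse_consensus("WHHDTG((N))KCACGWH"),
               class = "rhepipe_bad_consensus")
  expect_error(parse_consensus("WHHDTG(NN)KCACGWH"),
               class = "rhepipe_bad_consensus")
  expect_error(parse_consensus("WXHDTG"), class = "rhepipe_bad_consensus")
})

test_that("published hit patterns match the consensus in some orientation", {
  cons <- parse_consensus(RHE_RAW)
  patterns <- c(reported_rhe_hits()$hit_pattern, reported_rhe_patterns())
  for (p in patterns) {
    fwd <- match_at(p, 1, cons, nchar(p))
    rev <- match_at(p, 1, cons, nchar(p), orientation = "-")
    expect_true(fwd || rev, label = sprintf("pattern %s matches", p))
  }
  # a poly-A window fails: the consensus requires fixed C/G positions
  expect_false(match_at(strrep("A", 17), 1, cons, 17))
  expect_false(match_at(strrep("A", 17), 1, cons, 17, orientation = "-"))
  # forward-matching example from the published CDS rows
  expect_true(match_at("TCCATGGAAGTCACGAT", 1, cons, 17))
  # this promoter pattern only fits after reverse complement
  expect_false(match_at("TTCGTGAGTTTCAAATA", 1, cons, 17))
  expect_true(match_at("TTCGTGAGTTTCAAATA", 1, cons, 17, orientation = "-"))
})

test_that("region scanning equals the brute-force oracle on random sequences", {
  cons <- parse_consensus(RHE_RAW)
  withr::local_seed(51)
  for (rep in 1:40) {
    seq <- random_dna(500)
    # spike in forward and reverse instances so hits actually occur
    inst <- "TCCATGGAAGTCACGAT"
    substr(seq, 100, 116) <- inst
    substr(seq, 300, 316) <- oracle_revcomp(inst)
    got <- scan_region(seq, cons)
    want <- oracle_scan(seq, RHE_RAW)
    expect_identical(hit_key(got), hit_key(want))
  }
  expect_equal(nrow(scan_region("", cons)), 0L)
})

test_that("strand duality mirrors hits under reverse complement", {
  cons <- parse_consensus(RHE_RAW)
  withr::local_seed(52)
  for (rep in 1:10) {
    seq <- random_dna(400)
    substr(seq, 50, 66) <- "TCCATGGAAGTCACGAT"
    fwd <- scan_region(seq, cons)
    rev <- scan_region(oracle_revcomp(seq), cons)
    L_seq <- nchar(seq)
    mirrored <- vapply(seq_len(nrow(fwd)), function(i) {
      left <- min(fwd$start[i], fwd$end[i])
      len <- abs(fwd$start[i] - fwd$end[i]) + 1L
      m_left <- L_seq - left - len + 2L
      flip <- if (fwd$orientation[i] == "+") "-" else "+"
      any(pmin(rev$start, rev$end) == m_left & rev$orientation == flip &
            abs(rev$start - rev$end) + 1L == len)
    }, logical(1))
    expect_true(all(mirrored))
    expect_equal(nrow(fwd), nrow(rev))
  }
})

test_that("appending sequence never removes 5' hits", {
  cons <- parse_consensus(RHE_RAW)
  withr::local_seed(53)
  seq <- random_dna(300)
  substr(seq, 40, 56) <- "AAAGTGTAGAGCACGAT"
  base <- scan_region(seq, cons)
  longer <- scan_region(paste0(seq, random_dna(200)), cons)
  expect_true(all(hit_key(base) %in% hit_key(longer)))
})

test_that("gene scanning recovers planted truth and respects splicing", {
  cfg <- synth_config(seed = 55, n_scan_genes = 4, genome_len = 20000)
  gen <- gen_genome_with_motifs(cfg)
  hits <- scan_gene(gen$models, gen$genome, gen$consensus)
  expect_identical(gene_hit_key(hits), gene_hit_key(gen$truth))

  # missing chromosome errors
  expect_error(scan_gene(gen$models, c(ChrX = "ACGT"), gen$consensus),
               class = "rhepipe_missing_chromosome")

  # intronless gene: no intron hits possible
  lone <- gene_model("solo", "solo.1", "c", "+",
                     exons = rbind(c(3100L, 3400L)), cds = rbind(c(3100L, 3400L)))
  genome <- c(c = random_dna(4000))
  expect_false("intron" %in%
                 scan_gene(lone, genome, gen$consensus)$region)
})

test_that("a genomic hit straddling an exon-intron boundary is not a CDS hit", {
  cons <- parse_consensus(RHE_RAW)
  inst <- "TCCATGGAAGTCACGAT"
  withr::local_seed(57)
  # build a + strand gene whose exon1 ends mid-instance
  pre <- random_dna(3000 + 93)              # promoter + exon1 CDS before inst
  genome_txt <- paste0(pre, substr(inst, 1, 7), random_dna(100),
                       substr(inst, 8, 17), random_dna(200))
  model <- gene_model("bnd", "bnd.1", "cB", "+",
                      exons = rbind(c(3001L, 3100L), c(3201L, 3400L)),
                      cds = rbind(c(3001L, 3100L), c(3201L, 3400L)))
  genome <- c(cB = genome_txt)
  hits <- scan_gene(model, genome, cons)
  cds_hits <- hits[hits$region == "cds", ]
  # genomic text contains the split instance but the spliced CDS rejoins it
  expect_true(any(cds_hits$start == 94 & cds_hits$orientation == "+"))
  # and scanning the unspliced genomic CDS span finds nothing at that locus
  unspliced <- substr(genome_txt, 3001, 3400)
  expect_false(any(scan_region(unspliced, cons)$start == 94 &
                     scan_region(unspliced, cons)$orientation == "+"))
})

test_that("per-gene region combinations are labelled correctly", {
  hits <- tibble::tibble(
    gene_id = c("a", "a", "b", "b", "c", "c", "c"),
    transcript_id = NA_character_,
    region = c("promoter", "intron", "promoter", "promoter",
               "promoter", "intron", "cds"),
    region_index = c(0L, 1L, 0L, 0L, 0L, 2L, 0L),
    start = 1L, end = 17L, orientation = "+", matched_seq = "x")
  cls <- classify_genes(hits)
  expect_equal(cls$combination[cls$gene_id == "a"], "promoter+intron")
  expect_equal(cls$combination[cls$gene_id == "b"], "promoter-only")
  expect_equal(cls$n_promoter[cls$gene_id == "b"], 2L)
  expect_equal(cls$combination[cls$gene_id == "c"], "all-three")
  expect_equal(nrow(classify_genes(hits[0, ])), 0L)
})
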