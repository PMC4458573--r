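test_that("pearson wrapper matches hand values and the two-pass oracle", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)),
               class = "rhepipe_zero_variance")
  expect_error(pearson_cor(1:2, 1:2), class = "rhepipe_bad_argument")

  withr::local_seed(61)
  for (rep in 1:25) {
    x <- rnorm(sample(3:50, 1))
    y <- rnorm(length(x))
    expect_equal(pearson_cor(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("network construction thresholds edges and drops isolated genes", {
  withr::local_seed(62)
  mat <- matrix(rnorm(10 * 30), nrow = 10,
                dimnames = list(letters[1:10], NULL))
  # perfect duplicate survives any threshold
  mat["b", ] <- mat["a", ]
  net <- build_network(mat, threshold = 1)
  expect_equal(net$edges$from, "a")
  expect_equal(net$edges$to, "b")
  expect_equal(net$edges$weight, 1)
  expect_equal(net$nodes, c("a", "b"))      # isolated genes are not nodes
  expect_equal(net$n_input_genes, 10L)

  # every edge weight honours the cutoff; edge count decreases with threshold
  mat2 <- matrix(rnorm(20 * 40), nrow = 20,
                 dimnames = list(paste0("g", 1:20), NULL))
  counts <- vapply(c(0, 0.2, 0.4, 0.6), function(th) {
    n <- build_network(mat2, threshold = th)
    expect_true(all(n$edges$weight >= th))
    nrow(n$edges)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(build_network(mat2, genes = "nope"),
               class = "rhepipe_bad_argument")
})

test_that("planted modules are densely recovered at the study threshold", {
  cfg <- synth_config(seed = 63, n_genes = 120, n_arrays = 300,
                      module_specs = list(c(size = 15, latent_strength = 0.95)))
  comp <- gen_compendium(cfg)
  net <- build_network(comp$matrix, threshold = 0.83)
  members <- comp$truth[[1]]
  within <- net$edges$from %in% members & net$edges$to %in% members
  possible <- choose(length(members), 2)
  expect_gte(sum(within) / possible, 0.9)   # edge recall
  expect_equal(sum(!within), 0L)            # no background contamination
})

test_that("connected components partition the nodes deterministically", {
  edges <- tibble::tibble(from = c("a", "b", "x", "m"),
                          to = c("b", "c", "y", "n"),
                          weight = 0.9)
  net <- rhepipe:::new_network(edges, 0.83, 7L)
  comps <- connected_components(net)
  expect_equal(lengths(comps), c(3L, 2L, 2L))
  expect_equal(comps[[1]], c("a", "b", "c"))
  # tie of two 2-node components broken by smallest member
  expect_equal(comps[[2]], c("m", "n"))
  expect_true(all(unlist(comps) %in% net$nodes))
  expect_equal(sort(unlist(comps)), sort(net$nodes))
  expect_equal(connected_components(rhepipe:::new_network(edges[0, ], 0.8, 0L)),
               list())

  # two planted modules come out as two exact components
  cfg <- synth_config(seed = 64, n_genes = 40, n_arrays = 300,
                      module_specs = list(c(size = 12, latent_strength = 0.97),
                                          c(size = 7, latent_strength = 0.97)))
  comp <- gen_compendium(cfg)
  net2 <- build_network(comp$matrix, threshold = 0.83)
  comps2 <- connected_components(net2)
  expect_equal(length(comps2), 2L)
  expect_setequal(comps2[[1]], comp$truth[[1]])
  expect_setequal(comps2[[2]], comp$truth[[2]])
})

test_that("threshold sweep scores enrichment and breaks ties upward", {
  cfg <- synth_config(seed = 65, n_genes = 200, de_fraction = 0.2,
                      n_arrays = 300, dag_terms = 30,
                      enriched_term_size = 25,
                      module_specs = list(c(size = 20, latent_strength = 0.95)))
  comp <- gen_compendium(cfg)
  members <- comp$truth[[1]]
  genes <- rownames(comp$matrix)[1:80]
  go <- gen_go(cfg, study_genes = members)
  sw <- select_threshold(comp$matrix, genes, go$dag,
                         grid = seq(0.70, 0.90, 0.05))
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw$sweep), 5L)
  expect_true(sw$chosen %in% sw$sweep$threshold)
  expect_equal(max(sw$sweep$score),
               sw$sweep$score[sw$sweep$threshold == sw$chosen])
  # edge counts non-increasing across the grid
  expect_true(all(diff(sw$sweep$n_edges) <= 0))

  # grid of one value returns it
  one <- select_threshold(comp$matrix, genes, go$dag, grid = 0.8)
  expect_equal(one$chosen, 0.8)

  # flat noise: no enrichment anywhere, tie resolved to the largest value
  noise <- matrix(rnorm(30 * 300), nrow = 30,
                  dimnames = list(rownames(comp$matrix)[101:130], NULL))
  flat <- select_threshold(noise, rownames(noise), go$dag,
                           grid = c(0.05, 0.10))
  expect_equal(flat$sweep$score, c(0, 0))
  expect_equal(flat$chosen, 0.10)

  expect_error(select_threshold(noise, rownames(noise), go$dag,
                                grid = c(0.999, 1)),
               class = "rhepipe_empty_sweep")
})

test_that("bait-prey networks keep only bait-touching edges", {
  withr::local_seed(66)
  n_arr <- 50
  z <- rnorm(n_arr)
  mk <- function() 0.97 * z + sqrt(1 - 0.97^2) * rnorm(n_arr)
  mat <- rbind(b1 = mk(), b2 = mk(), p1 = mk(), p2 = mk(),
               lone = rnorm(n_arr))
  net <- bait_prey_network(mat, baits = c("b1", "b2"),
                           preys = c("p1", "p2", "lone"), threshold = 0.83)
  # the correlated prey pair p1-p2 must be gone despite r >= threshold
  expect_false(any(net$edges$from == "p1" & net$edges$to == "p2"))
  expect_true(cor(mat["p1", ], mat["p2", ]) >= 0.83)
  # every retained prey touches a bait
  roles <- setNames(net$roles$role, net$roles$node)
  for (p in net$roles$node[net$roles$role == "prey"]) {
    nb <- c(net$edges$to[net$edges$from == p],
            net$edges$from[net$edges$to == p])
    expect_true(any(roles[nb] == "bait"))
  }
  expect_false("lone" %in% net$nodes)
  expect_error(bait_prey_network(mat, c("b1"), c("b1", "p1")),
               class = "rhepipe_bad_argument")
})

test_that("network tidiers expose edges and summary rows", {
  edges <- tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                          weight = c(0.9, 0.85))
  net <- rhepipe:::new_network(edges, 0.83, 4L)
  expect_equal(tidy(net), edges)
  g <- glance(net)
  expect_equal(g$n_nodes, 3L)
  expect_equal(g$n_edges, 2L)
  expect_equal(g$n_components, 1L)
})
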