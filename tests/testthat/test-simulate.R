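test_that("generators are deterministic given their seed", {
  a <- simulate_activity(n_genes = 50, n1 = 10, n2 = 10, seed = 42)
  b <- simulate_activity(n_genes = 50, n1 = 10, n2 = 10, seed = 42)
  expect_identical(a$activity, b$activity)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    a$activity, simulate_activity(n_genes = 50, n1 = 10, n2 = 10,
                                  seed = 43)$activity))
})

test_that("null simulations plant nothing and extremes separate fully", {
  null <- simulate_activity(n_genes = 30, n_diff = 0, effect = 0, seed = 1)
  expect_false(any(null$truth$planted))
  expect_true(all(null$truth$p1 == null$truth$p2))

  extreme <- simulate_activity(n_genes = 10, n1 = 43, n2 = 43, base_prob = 0,
                               n_diff = 2, effect = 1, seed = 2)
  cnt <- activity_counts(extreme$activity, extreme$groups)
  g <- extreme$truth$gene[extreme$truth$direction == "group1"][1]
  row <- cnt[cnt$gene == g, ]
  expect_equal(c(row$n11, row$n21), c(43L, 0L))
  expect_lt(fisher_one_tailed(row$n11, row$n12, row$n21, row$n22,
                              "greater_first_cell"), 1e-10)
  expect_error(simulate_activity(base_prob = 0.8, effect = 0.4),
               "infeasible")
})

test_that("empirical activity rates track the generating probabilities", {
  sim <- simulate_activity(n_genes = 200, n1 = 150, n2 = 150, base_prob = 0.3,
                           n_diff = 40, effect = 0.4, seed = 7)
  cnt <- activity_counts(sim$activity, sim$groups)
  p1_hat <- cnt$n11 / 150
  se <- sqrt(sim$truth$p1 * (1 - sim$truth$p1) / 150)
  expect_true(all(abs(p1_hat - sim$truth$p1) <= 3.3 * se + 1e-9))
})

test_that("the PMA layer inverts exactly at zero flip probability", {
  sim <- simulate_activity(n_genes = 80, n1 = 12, n2 = 12, seed = 3)
  pma <- simulate_pma(sim$activity, probes_per_gene = 3, flip_prob = 0,
                      seed = 4)
  act <- probes_to_gene_activity(pma$pma, pma$probe_map, sim$groups)
  expect_equal(act, sim$activity[order(sim$activity$gene), ],
               ignore_attr = TRUE)

  solo <- simulate_pma(sim$activity, probes_per_gene = 1, seed = 5)
  expect_equal(nrow(solo$probe_map), 80L)
  expect_equal(anyDuplicated(solo$probe_map$gene), 0L)
})

test_that("spurious Present calls corrupt inactive cells at the closed-form rate", {
  sim <- simulate_activity(n_genes = 500, n1 = 20, n2 = 20, base_prob = 0.3,
                           n_diff = 0, effect = 0, seed = 6)
  k <- 4; flip <- 0.05
  pma <- simulate_pma(sim$activity, probes_per_gene = k, flip_prob = flip,
                      seed = 7)
  act <- probes_to_gene_activity(pma$pma, pma$probe_map, sim$groups)
  truth_m <- altpath:::act_matrix(sim$activity)
  got_m <- altpath:::act_matrix(act)[rownames(truth_m), colnames(truth_m)]
  inactive <- truth_m == 0L
  rate <- mean(got_m[inactive] == 1L)
  expected <- 1 - (1 - flip)^k
  n_inact <- sum(inactive)
  expect_lt(abs(rate - expected), 4 * sqrt(expected * (1 - expected) / n_inact))
  # active cells are never lost
  expect_true(all(got_m[truth_m == 1L] == 1L))
})

test_that("planted pathways are built from planted genes at the stated fraction", {
  sim <- simulate_activity(n_genes = 400, n_diff = 60, seed = 9)
  coll <- simulate_pathways(sim$truth, n_pathways = 30, n_enriched = 4,
                            set_size_range = c(20, 20),
                            enrichment_frac = 0.5, seed = 10)
  planted_genes <- sim$truth$gene[sim$truth$planted]
  hits <- vapply(coll$genes[coll$planted],
                 function(g) length(intersect(g, planted_genes)), integer(1))
  expect_true(all(hits >= 10))
  # null sets: hypergeometric composition around 20 * 60/400 = 3
  null_hits <- vapply(coll$genes[!coll$planted],
                      function(g) length(intersect(g, planted_genes)),
                      integer(1))
  expect_lt(mean(null_hits), 6)

  none <- simulate_pathways(sim$truth, n_pathways = 10, n_enriched = 0,
                            seed = 11)
  expect_false(any(none$planted))
})

test_that("DAG sampling respects the declared structure", {
  # empty graph: independent fair coins, balanced columns
  sim0 <- simulate_dag_data(n_nodes = 4, edge_prob = 0, n_samples = 2000,
                            seed = 12)
  m <- altpath:::act_matrix(sim0$activity)
  expect_true(all(abs(rowMeans(m) - 0.5) < 0.05))

  # single strong edge: high plug-in mutual information
  sim1 <- simulate_dag_data(n_samples = 2000, seed = 13,
                            edges = tibble::tibble(from = "A", to = "B"),
                            cpd_strength = 0.9)
  m1 <- altpath:::act_matrix(sim1$activity)
  tab <- table(m1["A", ], m1["B", ]) / 2000
  mi <- sum(tab * log(tab / (rowSums(tab) %o% colSums(tab))))
  expect_gt(mi, 0.2)
  expect_equal(mean(m1["A", ] == m1["B", ]), 0.9, tolerance = 0.05)

  # returned order is topological for the generated DAG
  simr <- simulate_dag_data(n_nodes = 8, edge_prob = 0.4, n_samples = 50,
                            seed = 14)
  pos <- setNames(seq_along(simr$activity$gene), simr$activity$gene)
  ed <- simr$truth$edges
  expect_true(all(pos[ed$from] < pos[ed$to]))
  expect_error(simulate_dag_data(cpd_strength = 0.4), "cpd_strength")
})
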