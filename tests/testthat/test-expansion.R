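toy_sets <- function(sets, universe) gene_set_collection(sets, universe)

chain_net <- function() {
  cpdag(c("a", "b", "c"),
        undirected = tibble::tibble(from = c("a", "b"), to = c("b", "c")))
}

test_that("one expansion step adds exactly the member neighbourhood", {
  coll <- toy_sets(list(s = "a"), c("a", "b", "c"))
  net <- chain_net()
  once <- expand_once(coll, net)
  expect_setequal(once$genes[[1]], c("a", "b"))
  twice <- expand_once(once, net)
  expect_setequal(twice$genes[[1]], c("a", "b", "c"))

  # empty network: identity
  empty <- cpdag(c("a", "b", "c"))
  expect_equal(set_list(expand_once(coll, empty)), set_list(coll))

  # network nodes outside the universe are ignored with a warning
  wide <- cpdag(c("a", "zz"), undirected = tibble::tibble(from = "a", to = "zz"))
  expect_warning(out <- expand_once(coll, wide), "outside the universe")
  expect_setequal(out$genes[[1]], "a")
})

test_that("directed edges expand in both directions", {
  net <- cpdag(c("a", "b", "c"),
               directed = tibble::tibble(from = c("a", "c"), to = c("b", "b")))
  coll <- toy_sets(list(s = "b"), c("a", "b", "c"))
  expect_setequal(expand_once(coll, net)$genes[[1]], c("a", "b", "c"))
})

test_that("the full expansion yields 1 + 2 * max_steps monotone collections", {
  universe <- letters[1:10]
  net1 <- cpdag(universe, undirected = tibble::tibble(from = letters[1:4],
                                                      to = letters[2:5]))
  net2 <- cpdag(universe, undirected = tibble::tibble(from = "f", to = "g"))
  coll <- toy_sets(list(s1 = "a", s2 = c("f", "h")), universe)

  res3 <- build_expansion(coll, net1, net2, max_steps = 3)
  expect_length(res3$collections, 7L)
  res1 <- build_expansion(coll, net1, net2, max_steps = 1)
  expect_length(res1$collections, 3L)

  # monotone growth within each condition
  for (cond in c("group1", "group2")) {
    prev <- set_list(coll)
    for (k in 1:3) {
      cur <- set_list(res3$collections[[paste0(cond, "_", k)]])
      for (nm in names(prev)) expect_true(all(prev[[nm]] %in% cur[[nm]]))
      prev <- cur
    }
  }

  # step-k sets equal the k-ball BFS oracle
  adj1 <- cpdag_adjlist(net1)
  for (k in 1:3) {
    got <- sort(set_list(res3$collections[[paste0("group1_", k)]])$s1)
    expect_equal(got, oracle_ball("a", adj1, k))
  }

  # saturation: s2's component {f, g} (plus isolated h) is reached at step 1
  expect_equal(set_list(res3$collections$group2_1)$s2,
               set_list(res3$collections$group2_3)$s2)
  expect_setequal(set_list(res3$collections$group2_3)$s2, c("f", "g", "h"))
})

test_that("identical networks give identical collections for both conditions", {
  universe <- letters[1:6]
  net <- cpdag(universe, undirected = tibble::tibble(from = c("a", "c"),
                                                     to = c("b", "d")))
  coll <- toy_sets(list(s = c("a", "c")), universe)
  res <- build_expansion(coll, net, net, max_steps = 2)
  expect_equal(set_list(res$collections$group1_1),
               set_list(res$collections$group2_1))
  expect_equal(set_list(res$collections$group1_2),
               set_list(res$collections$group2_2))
})

test_that("provenance records the step each gene joined at", {
  coll <- toy_sets(list(s = "a"), c("a", "b", "c"))
  res <- build_expansion(coll, chain_net(), cpdag(c("a", "b", "c")),
                         max_steps = 2)
  prov <- res$provenance
  expect_equal(prov$step_added[prov$gene == "b" & prov$condition == "group1"], 1L)
  expect_equal(prov$step_added[prov$gene == "c" & prov$condition == "group1"], 2L)
  expect_false(any(prov$condition == "group2" & prov$steps > 0))
})

test_that("condition-biased networks shift pathway significance accordingly", {
  # group1's network preferentially connects group1-active genes into the
  # sets, so the group1-expanded collection gains group1 significance
  sim <- simulate_activity(n_genes = 300, n_diff = 40, seed = 17)
  cls <- classify_genes(activity_counts(sim$activity, sim$groups))
  g1_active <- cls$gene[cls$class == "GROUP1_ACTIVE"]
  g2_active <- cls$gene[cls$class == "GROUP2_ACTIVE"]
  ns <- cls$gene[cls$class == "NS"]
  seed_genes <- ns[1:10]
  coll <- gene_set_collection(list(s = seed_genes), universe = cls$gene)
  link <- function(targets) {
    cpdag(cls$gene,
          undirected = tibble::tibble(
            from = rep(seed_genes, length.out = length(targets)),
            to = targets))
  }
  net1 <- link(head(g1_active, 10))
  net2 <- link(head(g2_active, 10))
  res <- build_expansion(coll, net1, net2, max_steps = 1)
  by_coll <- classify_expanded(res, cls)
  p_raw <- by_coll$p_g1[by_coll$collection == "raw"]
  p_exp1 <- by_coll$p_g1[by_coll$collection == "group1_1"]
  p_exp2_dir2 <- by_coll$p_g2[by_coll$collection == "group2_1"]
  expect_lt(p_exp1, p_raw)
  expect_lt(p_exp2_dir2, by_coll$p_g2[by_coll$collection == "raw"])
})
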