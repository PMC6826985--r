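test_that("overlap p-values match enumeration and the printed-variant identity", {
  expect_equal(overlap_pvalue(10, 10, 0, 100, "standard"), 1)
  expect_equal(overlap_pvalue(10, 10, 0, 100, "as_printed"), 1)
  expect_equal(overlap_pvalue(10, 10, 5, 100, "standard"),
               oracle_overlap(10, 10, 5, 100), tolerance = 1e-12)
  withr::with_seed(55, {
    for (rep in 1:100) {
      nall <- sample1(5:60)
      na <- sample1(1:nall); nb <- sample1(1:nall)
      lo <- max(0, na + nb - nall)
      nab <- sample1(lo:min(na, nb))
      expect_equal(overlap_pvalue(na, nb, nab, nall, "standard"),
                   oracle_overlap(na, nb, nab, nall), tolerance = 1e-12)
      # standard - as_printed = -P(X = 0); at nab = 0 both sums are empty
      # and the two variants coincide at 1
      if (nab >= 1) {
        diff <- overlap_pvalue(na, nb, nab, nall, "standard") -
          overlap_pvalue(na, nb, nab, nall, "as_printed")
        expect_lt(abs(diff + oracle_overlap_pmf(na, nb, 0, nall)), 1e-12)
      }
    }
  })
  expect_error(overlap_pvalue(10, 10, 11, 100), "infeasible")
  expect_error(overlap_pvalue(50, 60, 0, 100), "infeasible")
})

test_that("BH step-up matches the reference implementation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  withr::with_seed(6, {
    for (rep in 1:50) {
      p <- runif(sample(1:200, 1))
      q <- bh_fdr(p)
      expect_equal(q, stats::p.adjust(p, method = "fdr"), tolerance = 1e-12)
      expect_true(all(diff(sort(q)) >= -1e-15))
    }
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_classes <- function(sets, sig) {
  tibble::tibble(pathway = names(sets),
                 significant_g1 = names(sets) %in% sig,
                 significant_g2 = FALSE,
                 p_g1 = ifelse(names(sets) %in% sig, 0.001, 0.5),
                 p_g2 = 0.5,
                 class = ifelse(names(sets) %in% sig, "group1", "NS"))
}

test_that("disjoint pathways yield no edges; identical pathways a certain edge", {
  universe <- sprintf("u%03d", 1:200)
  sets <- list(A = universe[1:20], B = universe[21:40], C = universe[1:20])
  coll <- gene_set_collection(sets, universe)
  pc <- make_classes(sets, c("A", "B", "C"))
  net <- build_pathway_network(pc, coll)
  keys <- paste(net$edges$pathway_a, net$edges$pathway_b)
  expect_true("A C" %in% keys)        # identical sets: overlap certain
  expect_false("A B" %in% keys)       # disjoint
  ac <- net$edges[net$edges$pathway_a == "A" & net$edges$pathway_b == "C", ]
  expect_equal(ac$p, oracle_overlap(20, 20, 20, ac$nall), tolerance = 1e-12)
  expect_lt(ac$p, 1e-9)
})

test_that("fewer than two significant pathways gives an empty network", {
  universe <- sprintf("u%03d", 1:50)
  sets <- list(A = universe[1:10], B = universe[11:20])
  coll <- gene_set_collection(sets, universe)
  expect_warning(net <- build_pathway_network(make_classes(sets, "A"), coll),
                 "fewer than 2")
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(net$nodes), 1L)
})

test_that("raising the FDR threshold never removes an edge", {
  withr::with_seed(23, {
    universe <- sprintf("u%03d", 1:150)
    sets <- setNames(lapply(1:12, function(i) sample(universe, 25)),
                     paste0("P", 1:12))
    coll <- gene_set_collection(sets, universe)
    pc <- make_classes(sets, names(sets))
    lo <- build_pathway_network(pc, coll, fdr_threshold = 0.02)
    hi <- build_pathway_network(pc, coll, fdr_threshold = 0.2)
    expect_true(all(altpath:::edge_keys(lo$edges) %in%
                      altpath:::edge_keys(hi$edges)))
  })
})

test_that("q-values dominate p-values and the family is the tested pairs", {
  universe <- sprintf("u%03d", 1:100)
  sets <- list(A = universe[1:30], B = universe[20:45], C = universe[40:70],
               D = universe[65:95])
  coll <- gene_set_collection(sets, universe)
  net <- build_pathway_network(make_classes(sets, names(sets)), coll,
                               fdr_threshold = 1)
  expect_equal(nrow(net$all_pairs), choose(4, 2))
  expect_true(all(net$all_pairs$q >= net$all_pairs$p - 1e-15))
  expect_equal(net$all_pairs$q,
               stats::p.adjust(net$all_pairs$p, "fdr"), tolerance = 1e-12)
})

test_that("network comparison is exact set algebra with degree-ranked hubs", {
  mk <- function(edges) {
    altpath:::new_pathway_network(
      tibble::tibble(pathway = unique(c(edges$pathway_a, edges$pathway_b)),
                     class = "group1", size = 10L, p_g1 = 0.01, p_g2 = 0.5),
      edges, edges, 0.05, "standard")
  }
  ea <- tibble::tibble(pathway_a = c("P1", "P1", "P2", "P3", "P4"),
                       pathway_b = c("P2", "P3", "P3", "P4", "P5"),
                       na = 10L, nb = 10L, nab = 5L, nall = 50L,
                       p = 0.01, q = 0.02)
  eb <- ea[c(1, 3), ]
  cmp <- compare_networks(mk(ea), mk(eb))
  expect_equal(nrow(cmp$common), 2L)
  expect_equal(nrow(cmp$a_specific), 3L)
  expect_equal(nrow(cmp$b_specific), 0L)
  hubs_a <- cmp$hubs[cmp$hubs$network == "a", ]
  expect_equal(hubs_a$pathway[1], names(which.max(
    table(c(cmp$a_specific$pathway_a, cmp$a_specific$pathway_b)))))

  same <- compare_networks(mk(ea), mk(ea))
  expect_equal(nrow(same$a_specific), 0L)
  expect_equal(nrow(same$b_specific), 0L)
})
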