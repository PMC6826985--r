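mk_counts <- function(c1, c2, gene_a = "A", gene_b = "B") {
  structure(tibble::tibble(role = rep(c("group1", "group2"), each = 4),
                           state = rep(c("00", "01", "10", "11"), 2),
                           n = as.integer(c(c1, c2))),
            gene_a = gene_a, gene_b = gene_b,
            class = c("pair_state_counts", "tbl_df", "tbl", "data.frame"))
}

test_that("joint-state counts are tallied per group and conserve group size", {
  m <- rbind(A = c(1, 1, 1, 0, 0, 0), B = c(0, 0, 0, 0, 1, 1))
  act <- make_activity(m, c("A", "B"), sprintf("s%d", 1:6))
  sg <- make_groups(sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  psc <- pair_state_counts(act, sg, "A", "B")
  tab <- altpath:::psc_matrix(psc)
  expect_equal(tab["group1", "10"], 3L)   # A always active, B inactive
  expect_equal(tab["group2", c("00", "01")], c("00" = 1L, "01" = 2L))
  expect_equal(rowSums(tab), c(group1 = 3L, group2 = 3L))
  expect_error(pair_state_counts(act, sg, "A", "Z"), "gene 'Z'")
})

test_that("counts equal a per-sample recount on simulated data", {
  sim <- simulate_activity(n_genes = 30, n1 = 21, n2 = 22, n_diff = 10, seed = 1)
  act <- sim$activity
  psc <- pair_state_counts(act, sim$groups, "g0003", "g0010")
  tab <- altpath:::psc_matrix(psc)
  a <- unlist(act[act$gene == "g0003", -1])
  b <- unlist(act[act$gene == "g0010", -1])
  st <- paste0(a, b)
  g1 <- names(a) %in% group_members(sim$groups, "group1")
  for (s in c("00", "01", "10", "11")) {
    expect_equal(tab["group1", s], sum(st == s & g1))
    expect_equal(tab["group2", s], sum(st == s & !g1))
  }
})

test_that("transition tests match enumeration and detect planted inversions", {
  cnt <- mk_counts(c(5, 5, 30, 3), c(3, 30, 5, 5))
  tt <- test_transition(cnt, "10", "01")
  expect_equal(tt$p_value, oracle_fisher(30, 5, 5, 30, "greater"),
               tolerance = 1e-12)
  expect_true(tt$significant)
  expect_equal(tt$pattern_type, 4L)

  # symmetric counts can never be significant
  sym <- mk_counts(c(10, 12, 9, 12), c(10, 12, 9, 12))
  tts <- transition_table(sym)
  expect_true(all(tts$p_value >= 0.5))

  # both relevant rows all-zero: p = 1
  z <- mk_counts(c(43, 0, 0, 0), c(43, 0, 0, 0))
  expect_equal(test_transition(z, "01", "10")$p_value, 1)
})

test_that("the 12 ordered transitions partition into types 8/2/2", {
  cnt <- mk_counts(rep(5, 4), rep(5, 4))
  tt <- transition_table(cnt)
  expect_equal(nrow(tt), 12L)
  expect_equal(as.integer(table(tt$pattern_type)[c("2", "3", "4")]),
               c(8L, 2L, 2L))
})

test_that("pattern assignment gates on Step-1 classes and takes the minimal p", {
  cnt <- mk_counts(c(12, 22, 3, 6), c(3, 4, 24, 12))
  # gate: both genes NS -> Pattern 1, nothing tested
  gated <- assign_pattern(cnt, "NS", "NS")
  expect_equal(gated$assigned, "PATTERN1")
  expect_false(gated$tested)

  res <- assign_pattern(cnt, "GROUP1_ACTIVE", "NS")
  tt <- transition_table(cnt)
  sig <- tt[tt$significant, ]
  expect_equal(res$min_p, min(sig$p_value))
  expect_equal(res$assigned,
               paste0(sig$from[which.min(sig$p_value)], "->",
                      sig$to[which.min(sig$p_value)]))
})

test_that("group swap reverses every assignment with identical p", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      c1 <- as.integer(stats::rmultinom(1, 40, runif(4)))
      c2 <- as.integer(stats::rmultinom(1, 40, runif(4)))
      fwd <- transition_table(mk_counts(c1, c2))
      rev <- transition_table(mk_counts(c2, c1))
      key_f <- paste(fwd$from, fwd$to)
      key_r <- paste(rev$to, rev$from)
      expect_equal(fwd$p_value, rev$p_value[match(key_f, key_r)])
    }
  })
})

test_that("pattern scan recovers planted inversions and respects the gate", {
  # 20 pairs: 5 planted inversions (group1 state 01 dominant, group2 10
  # dominant), 15 null pairs with identical mixtures in both groups
  n1 <- 43; n2 <- 43
  genes <- sprintf("q%02d", 1:40)
  withr::with_seed(1, {
    m <- matrix(0L, 40, n1 + n2,
                dimnames = list(genes, sprintf("s%02d", 1:(n1 + n2))))
    for (k in 1:20) {
      a <- 2 * k - 1; b <- 2 * k
      if (k <= 5) {
        m[a, 1:n1] <- rbinom(n1, 1, 0.1);  m[b, 1:n1] <- rbinom(n1, 1, 0.9)
        m[a, (n1 + 1):(n1 + n2)] <- rbinom(n2, 1, 0.9)
        m[b, (n1 + 1):(n1 + n2)] <- rbinom(n2, 1, 0.1)
      } else {
        m[a, ] <- rbinom(n1 + n2, 1, 0.5)
        m[b, ] <- rbinom(n1 + n2, 1, 0.5)
      }
    }
  })
  act <- make_activity(m, genes, sprintf("s%02d", 1:(n1 + n2)))
  sg <- make_groups(sprintf("s%02d", 1:n1), sprintf("s%02d", (n1 + 1):(n1 + n2)))
  pairs <- tibble::tibble(gene_a = genes[seq(1, 39, 2)],
                          gene_b = genes[seq(2, 40, 2)])
  cls <- classify_genes(activity_counts(act, sg))
  res <- pattern_scan(act, pairs, sg, cls)
  planted <- res[res$gene_a %in% genes[seq(1, 9, 2)], ]
  expect_gte(sum(planted$assigned == "01->10"), 4L)

  # empty pair list -> empty report; unmeasured genes skipped with warning
  expect_equal(nrow(pattern_scan(act, pairs[0, ], sg, cls)), 0L)
  expect_warning(
    res2 <- pattern_scan(act, tibble::tibble(gene_a = "nope", gene_b = "q01"),
                         sg, cls),
    "unmeasured")
  expect_equal(nrow(res2), 0L)
})

test_that("identical groups yield Pattern 1 for every pair", {
  m <- matrix(rep(c(1L, 0L), each = 20), nrow = 2, byrow = TRUE)
  m <- rbind(m, m)
  act <- make_activity(m, c("A", "B", "C", "D"), sprintf("s%d", 1:20))
  sg <- make_groups(sprintf("s%d", 1:10), sprintf("s%d", 11:20))
  cls <- classify_genes(activity_counts(act, sg))
  res <- pattern_scan(act, tibble::tibble(gene_a = c("A", "C"),
                                          gene_b = c("B", "D")),
                      sg, cls, gate = FALSE)
  expect_true(all(res$assigned == "PATTERN1"))
})

test_that("node report lists per-class members and flags alternative nodes", {
  node_map <- tibble::tibble(
    pathway = "calcium",
    node = c(rep("CALM", 4), rep("DEAD", 2)),
    gene = c("CALM2", "CALML5", "CALML3", "CALML6", "X1", "X2"))
  gc <- tibble::tibble(
    gene = c("CALM2", "CALML5", "CALML3", "CALML6", "X1", "X2"),
    class = c("GROUP1_ACTIVE", "GROUP1_ACTIVE",
              "GROUP2_ACTIVE", "GROUP2_ACTIVE", "NS", "NS"))
  rep <- node_activity_report(node_map, gc)
  calm <- rep[rep$node == "CALM", ]
  expect_equal(calm$group1_active, "CALM2,CALML5")
  expect_equal(calm$group2_active, "CALML3,CALML6")
  expect_true(calm$alternative)
  dead <- rep[rep$node == "DEAD", ]
  expect_equal(dead$group1_active, "")
  expect_false(dead$alternative)

  # relational-join oracle on a simulated class table
  sim <- simulate_activity(n_genes = 100, n1 = 20, n2 = 20, seed = 3)
  cls <- classify_genes(activity_counts(sim$activity, sim$groups))
  nm <- tibble::tibble(pathway = "p", node = rep(c("n1", "n2"), each = 5),
                       gene = cls$gene[1:10])
  got <- node_activity_report(nm, cls)
  for (nd in c("n1", "n2")) {
    members <- nm$gene[nm$node == nd]
    want <- sort(members[cls$class[match(members, cls$gene)] == "GROUP1_ACTIVE"])
    expect_equal(got$group1_active[got$node == nd], paste(want, collapse = ","))
  }
})
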