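# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, at the study's design scale
# (balanced 43/43 groups; imbalanced 153/43 for robustness work) but with
# reduced gene counts. Activity is sampled independently across genes and
# samples -- the exchangeability the Fisher exact test assumes; correlated
# genes are available only through simulate_dag_data().

#' Simulate a two-group binary activity profile with planted signal
#'
#' Each gene is active in a sample with a group-specific Bernoulli
#' probability. Non-planted genes share `p1 = p2 = base_prob`; the `n_diff`
#' planted genes get an activity-probability gap of `effect`, half of them
#' more active in group1 (`p1 = base_prob + effect`) and half in group2.
#'
#' @param n_genes Number of genes.
#' @param n1,n2 Group sizes (defaults 43/43, the balanced design).
#' @param base_prob Baseline activity probability.
#' @param n_diff Number of planted differentially-active genes.
#' @param effect Activity-probability gap for planted genes.
#' @param seed Integer seed.
#' @param labels Group labels, group1 first.
#' @return List of class `activity_sim`: `activity` (tibble), `groups`
#'   ([sample_groups()]), `truth` (tibble `gene`, `p1`, `p2`, `planted`,
#'   `direction`).
#' @export
simulate_activity <- function(n_genes = 1000, n1 = 43, n2 = 43,
                              base_prob = 0.3, n_diff = 50, effect = 0.4,
                              seed = 1,
                              labels = c("primary", "metastatic")) {
  if (base_prob < 0 || base_prob > 1 ||
      base_prob + effect > 1 || base_prob + effect < 0) {
    abort("infeasible probabilities: need base_prob and base_prob + effect in [0, 1]")
  }
  if (n_diff > n_genes) abort("n_diff exceeds n_genes")
  withr::with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- c(sprintf("%s_%03d", labels[1], seq_len(n1)),
                 sprintf("%s_%03d", labels[2], seq_len(n2)))
    groups <- sample_groups(tibble(sample_id = samples,
                                   group = rep(labels, c(n1, n2))),
                            group1 = labels[1])
    planted <- sort(sample(n_genes, n_diff))
    direction <- rep("none", n_genes)
    if (n_diff > 0L) {
      up1 <- planted[seq_len(ceiling(n_diff / 2))]
      direction[up1] <- "group1"
      direction[setdiff(planted, up1)] <- "group2"
    }
    p1 <- rep(base_prob, n_genes)
    p2 <- rep(base_prob, n_genes)
    p1[direction == "group1"] <- base_prob + effect
    p2[direction == "group2"] <- base_prob + effect
    m1 <- matrix(rbinom(n_genes * n1, 1, rep(p1, n1)), nrow = n_genes)
    m2 <- matrix(rbinom(n_genes * n2, 1, rep(p2, n2)), nrow = n_genes)
    m <- cbind(m1, m2)
    dimnames(m) <- list(genes, samples)
    structure(list(activity = dplyr::bind_cols(tibble(gene = genes),
                                               as_tibble(m)),
                   groups = groups,
                   truth = tibble(gene = genes, p1 = p1, p2 = p2,
                                  planted = direction != "none",
                                  direction = direction)),
              seed = seed, class = "activity_sim")
  })
}

#' Emit a probe-level PMA table realising an activity profile
#'
#' Each gene gets `probes_per_gene` probes. In a sample where the gene is
#' active, at least one probe carries a Present call; where it is inactive
#' every probe carries Marginal or Absent, except that each probe
#' independently flips to a spurious Present with probability `flip_prob`.
#' With `flip_prob = 0`, [probes_to_gene_activity()] recovers the input
#' profile exactly; otherwise an inactive cell is mis-recovered with
#' probability `1 - (1 - flip_prob)^probes_per_gene`.
#'
#' @param activity An activity table.
#' @param probes_per_gene Probes per gene (>= 1).
#' @param flip_prob Spurious-Present probability per inactive probe.
#' @param seed Integer seed.
#' @return List: `pma` (tibble probe x sample of `P`/`M`/`A`) and
#'   `probe_map` (tibble `probe_id`, `gene`).
#' @export
simulate_pma <- function(activity, probes_per_gene = 2, flip_prob = 0,
                         seed = 1) {
  if (probes_per_gene < 1L) abort("probes_per_gene must be >= 1")
  m <- act_matrix(activity)
  withr::with_seed(seed, {
    genes <- rownames(m)
    k <- probes_per_gene
    probe_ids <- paste0(rep(genes, each = k), "_p", rep(seq_len(k), length(genes)))
    calls <- matrix("A", nrow = length(probe_ids), ncol = ncol(m),
                    dimnames = list(NULL, colnames(m)))
    for (s in seq_len(ncol(m))) {
      # inactive background: M or A, with spurious P at flip_prob
      bg <- sample(c("M", "A"), length(probe_ids), replace = TRUE,
                   prob = c(0.2, 0.8))
      if (flip_prob > 0) {
        bg[runif(length(probe_ids)) < flip_prob] <- "P"
      }
      calls[, s] <- bg
      active_genes <- which(m[, s] == 1L)
      for (g in active_genes) {
        rows <- (g - 1L) * k + seq_len(k)
        on <- runif(k) < 0.5
        if (!any(on)) on[sample.int(k, 1L)] <- TRUE
        calls[rows[on], s] <- "P"
      }
    }
    list(pma = dplyr::bind_cols(tibble(probe_id = probe_ids),
                                as_tibble(calls)),
         probe_map = tibble(probe_id = probe_ids,
                            gene = rep(genes, each = k)))
  })
}

#' Simulate pathway gene sets with planted enrichment
#'
#' `n_enriched` pathways draw a fraction `enrichment_frac` of their members
#' from the planted differentially-active genes of an [simulate_activity()]
#' truth table; the remaining members, and all members of the other
#' pathways, are drawn uniformly from the universe.
#'
#' @param truth Truth tibble from [simulate_activity()].
#' @param n_pathways Number of gene sets.
#' @param set_size_range Inclusive range of set sizes.
#' @param n_enriched Number of planted (enriched) pathways.
#' @param enrichment_frac Fraction of an enriched set drawn from planted genes.
#' @param seed Integer seed.
#' @return A [gene_set_collection()] with an extra column `planted`.
#' @export
simulate_pathways <- function(truth, n_pathways = 50,
                              set_size_range = c(15, 40),
                              n_enriched = 5, enrichment_frac = 0.5,
                              seed = 1) {
  if (n_enriched > n_pathways) abort("n_enriched exceeds n_pathways")
  universe <- truth$gene
  planted_genes <- truth$gene[truth$planted]
  withr::with_seed(seed, {
    size_opts <- seq(set_size_range[1], set_size_range[2])
    sizes <- size_opts[sample.int(length(size_opts), n_pathways,
                                  replace = TRUE)]
    names <- sprintf("PW%03d", seq_len(n_pathways))
    enriched <- seq_len(n_enriched)
    sets <- lapply(seq_len(n_pathways), function(i) {
      s <- sizes[i]
      if (i %in% enriched && length(planted_genes) > 0L) {
        k <- min(round(s * enrichment_frac), length(planted_genes))
        core <- sample(planted_genes, k)
        rest <- sample(setdiff(universe, core), s - k)
        c(core, rest)
      } else {
        sample(universe, s)
      }
    })
    coll <- gene_set_collection(setNames(sets, names), universe)
    coll$planted <- coll$set_name %in% names[enriched]
    coll
  })
}

#' Sample binary data from a random (or given) DAG
#'
#' Ground truth for structure-recovery experiments. The DAG is drawn as an
#' ordered Erdos-Renyi graph (edges only forward in node order) unless an
#' explicit edge table is supplied. Roots are fair coins; a child copies the
#' majority vote of its parents with probability `cpd_strength` and flips it
#' otherwise (exact ties resolve by a fair coin), so a single strong edge
#' gives `P(child = parent) = cpd_strength`. Samples are drawn ancestrally.
#'
#' @param n_nodes Number of nodes (ignored when `edges` is given and names
#'   cover it).
#' @param edge_prob Forward edge probability for the random DAG.
#' @param cpd_strength Parent-copy probability in (0.5, 1].
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param edges Optional explicit DAG edge tibble (`from`, `to`), must be
#'   acyclic.
#' @return List of class `dag_sim`: `activity` (genes x samples tibble),
#'   `truth` (list with `edges` tibble and `order`).
#' @export
simulate_dag_data <- function(n_nodes = 10, edge_prob = 0.3,
                              cpd_strength = 0.9, n_samples = 1000,
                              seed = 1, edges = NULL) {
  if (cpd_strength <= 0.5 || cpd_strength > 1) {
    abort("cpd_strength must lie in (0.5, 1]")
  }
  withr::with_seed(seed, {
    if (is.null(edges)) {
      nodes <- sprintf("n%02d", seq_len(n_nodes))
      em <- matrix(FALSE, n_nodes, n_nodes)
      for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
        if (i < j && runif(1) < edge_prob) em[i, j] <- TRUE
      }
      idx <- which(em, arr.ind = TRUE)
      edges <- tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]])
    } else {
      stopifnot(all(c("from", "to") %in% names(edges)))
      edges <- as_tibble(edges[c("from", "to")])
      nodes <- sort(unique(c(edges$from, edges$to)))
      # topological order check via the cpdag validator
      invisible(cpdag(nodes, directed = edges))
      nodes <- topo_order(nodes, edges)
    }
    p <- length(nodes)
    X <- matrix(0L, nrow = n_samples, ncol = p, dimnames = list(NULL, nodes))
    for (v in nodes) {
      pa <- edges$from[edges$to == v]
      if (length(pa) == 0L) {
        X[, v] <- rbinom(n_samples, 1, 0.5)
      } else {
        votes <- rowSums(X[, pa, drop = FALSE])
        base <- ifelse(votes * 2L > length(pa), 1L,
                       ifelse(votes * 2L < length(pa), 0L,
                              rbinom(n_samples, 1, 0.5)))
        copy <- rbinom(n_samples, 1, cpd_strength)
        X[, v] <- ifelse(copy == 1L, base, 1L - base)
      }
    }
    rownames(X) <- sprintf("s%04d", seq_len(n_samples))
    structure(list(activity = dplyr::bind_cols(tibble(gene = nodes),
                                               as_tibble(t(X))),
                   truth = list(edges = edges, order = nodes)),
              seed = seed, class = "dag_sim")
  })
}

topo_order <- function(nodes, edges) {
  order <- character(0)
  remaining <- nodes
  e <- edges
  while (length(remaining) > 0L) {
    roots <- setdiff(remaining, e$to)
    if (length(roots) == 0L) abort("edge table contains a cycle")
    order <- c(order, sort(roots))
    remaining <- setdiff(remaining, roots)
    e <- e[!e$from %in% roots, , drop = FALSE]
  }
  order
}
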