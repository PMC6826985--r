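# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: tail probabilities come from explicit
# binomial-coefficient sums, graph questions from small standalone routines.

# draw one element of a vector (sample() treats a scalar as 1:n)
sample1 <- function(v) v[sample.int(length(v), 1L)]

# exact one-tailed Fisher p by enumerating every first-cell value compatible
# with the margins of [[a, b], [c, d]]
oracle_fisher <- function(a, b, c, d, tail = "greater") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  i <- lo:hi
  pmf <- exp(lchoose(r1, i) + lchoose(r2, c1 - i) - lchoose(n, c1))
  if (tail == "greater") sum(pmf[i >= a]) else sum(pmf[i <= a])
}

# exact overlap tail P(X >= nab) by explicit pmf summation
oracle_overlap <- function(na, nb, nab, nall) {
  lo <- max(0L, na + nb - nall); hi <- min(na, nb)
  i <- lo:hi
  pmf <- exp(lchoose(na, i) + lchoose(nall - na, nb - i) - lchoose(nall, nb))
  sum(pmf[i >= nab])
}

# hypergeometric point mass P(X = k) for the overlap test
oracle_overlap_pmf <- function(na, nb, k, nall) {
  exp(lchoose(na, k) + lchoose(nall - na, nb - k) - lchoose(nall, nb))
}

# k-step BFS ball of a seed set in an undirected adjacency list
oracle_ball <- function(seed, adj, k) {
  cur <- seed
  for (step in seq_len(k)) {
    nb <- unique(unlist(adj[cur], use.names = FALSE))
    cur <- union(cur, nb)
  }
  sort(cur)
}

# adjacency list (both edge directions) of a cpdag, for the BFS oracle
cpdag_adjlist <- function(net) {
  edges <- rbind(as.matrix(net$directed), as.matrix(net$undirected))
  adj <- setNames(vector("list", length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
    adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
  }
  adj
}

# ---- standalone pattern (CPDAG) computation for the GES class oracle ------
# dag: logical adjacency matrix. Returns list(dir, und) after orienting
# v-structures and closing under the orientation rules. Written separately
# from the package's internals on purpose.
oracle_pattern <- function(dag) {
  p <- nrow(dag)
  skel <- dag | t(dag)
  dir <- matrix(FALSE, p, p)
  for (y in 1:p) {
    pa <- which(dag[, y])
    if (length(pa) >= 2) {
      for (i in pa) for (j in pa) {
        if (i < j && !skel[i, j]) { dir[i, y] <- TRUE; dir[j, y] <- TRUE }
      }
    }
  }
  und <- skel & !(dir | t(dir))
  repeat {
    changed <- FALSE
    sk <- dir | t(dir) | und
    for (b in 1:p) for (cc in 1:p) {
      if (!und[b, cc]) next
      fire <- FALSE
      a_in <- which(dir[, b])
      if (any(a_in != cc & !sk[a_in, cc])) fire <- TRUE
      if (!fire && any(dir[b, ] & dir[, cc])) fire <- TRUE
      if (!fire) {
        ds <- which(und[b, ] & dir[, cc])
        if (length(ds) >= 2) {
          for (i in ds) for (j in ds) if (i < j && !sk[i, j]) fire <- TRUE
        }
      }
      if (fire) {
        und[b, cc] <- und[cc, b] <- FALSE
        dir[b, cc] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(dir = dir, und = und)
}

# all 25 DAGs on 3 labelled nodes, as logical adjacency matrices
all_dags_3 <- function() {
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    m <- matrix(FALSE, 3, 3)
    st <- c(s1, s2, s3)
    for (k in 1:3) {
      if (st[k] == 1) m[pairs[k, 1], pairs[k, 2]] <- TRUE
      if (st[k] == 2) m[pairs[k, 2], pairs[k, 1]] <- TRUE
    }
    # cyclic only possible with all three edges
    if (sum(st > 0) == 3) {
      reach <- m
      for (r in 1:3) reach <- reach | (reach %*% m > 0)
      if (any(diag(reach))) next
    }
    out[[length(out) + 1L]] <- m
  }
  out
}

# decomposable saturated-Bernoulli BIC of a DAG, computed independently
oracle_dag_score <- function(dag, dat, pd) {
  n <- nrow(dat)
  total <- 0
  for (j in seq_len(ncol(dag))) {
    pa <- which(dag[, j])
    y <- dat[, j]
    if (length(pa) == 0) {
      cfg <- rep(1L, n)
      ncfg <- 1L
    } else {
      cfg <- as.integer(dat[, pa, drop = FALSE] %*% 2^(seq_along(pa) - 1)) + 1L
      ncfg <- 2L^length(pa)
    }
    ll <- 0
    for (cg in seq_len(ncfg)) {
      idx <- cfg == cg
      m <- sum(idx)
      if (m == 0) next
      m1 <- sum(y[idx])
      for (cnt in c(m1, m - m1)) if (cnt > 0) ll <- ll + cnt * log(cnt / m)
    }
    total <- total + ll - pd * (2^length(pa) / 2) * log(n)
  }
  total
}

# edge-set view of a cpdag for comparisons against oracle_pattern output
cpdag_edge_sets <- function(net, nodes) {
  idx <- function(x) match(x, nodes)
  dir <- matrix(FALSE, length(nodes), length(nodes))
  und <- dir
  if (nrow(net$directed) > 0) {
    dir[cbind(idx(net$directed$from), idx(net$directed$to))] <- TRUE
  }
  if (nrow(net$undirected) > 0) {
    und[cbind(idx(net$undirected$from), idx(net$undirected$to))] <- TRUE
    und[cbind(idx(net$undirected$to), idx(net$undirected$from))] <- TRUE
  }
  list(dir = dir, und = und)
}

# tiny deterministic activity table builder: rows gene, cols s1..sn
make_activity <- function(mat, genes, samples) {
  dimnames(mat) <- list(genes, samples)
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(mat))
}

make_groups <- function(samples1, samples2, labels = c("g1", "g2")) {
  sample_groups(
    tibble::tibble(sample_id = c(samples1, samples2),
                   group = rep(labels, c(length(samples1), length(samples2)))),
    group1 = labels[1])
}
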