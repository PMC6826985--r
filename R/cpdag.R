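# Completed partially directed acyclic graphs (patterns): the output of
# greedy equivalence search. Internal representation is a pair of logical
# matrices (dir[i, j] = i -> j; und symmetric) over a fixed node order;
# the user-facing object stores edge tibbles.

#' Construct a CPDAG from edge tables
#'
#' @param nodes Character vector of node names.
#' @param directed Data frame with columns `from`, `to` (i -> j edges).
#' @param undirected Data frame with columns `from`, `to` (order irrelevant).
#' @return An object of class `cpdag` with fields `nodes`, `directed`,
#'   `undirected` (undirected edges stored with `from < to`).
#' @export
cpdag <- function(nodes, directed = NULL, undirected = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node names")
  ed <- normalise_edges(directed, nodes)
  eu <- normalise_edges(undirected, nodes)
  if (nrow(eu) > 0L) {
    flip <- eu$from > eu$to
    tmp <- eu$from[flip]; eu$from[flip] <- eu$to[flip]; eu$to[flip] <- tmp
    eu <- dplyr::distinct(eu)
  }
  if (any(ed$from == ed$to) || any(eu$from == eu$to)) abort("self-loops not allowed")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  dup_dir <- duplicated(key(ed$from, ed$to))
  if (any(dup_dir)) abort("contradictory duplicate directed edges (2-cycle or repeat)")
  if (length(intersect(key(ed$from, ed$to), key(eu$from, eu$to))) > 0L) {
    abort("an edge cannot be both directed and undirected")
  }
  x <- structure(list(nodes = nodes,
                      directed = ed,
                      undirected = eu),
                 class = "cpdag")
  if (has_directed_cycle(x)) abort("directed subgraph contains a cycle")
  x
}

normalise_edges <- function(e, nodes) {
  if (is.null(e) || (is.data.frame(e) && nrow(e) == 0L)) {
    return(tibble(from = character(), to = character()))
  }
  stopifnot(is.data.frame(e), all(c("from", "to") %in% names(e)))
  e <- as_tibble(e[c("from", "to")])
  e$from <- as.character(e$from); e$to <- as.character(e$to)
  unknown <- setdiff(c(e$from, e$to), nodes)
  if (length(unknown) > 0L) {
    abort(sprintf("edge endpoint(s) not in node set: %s",
                  paste(head(unknown, 5L), collapse = ", ")))
  }
  dplyr::distinct(e)
}

#' @export
print.cpdag <- function(x, ...) {
  cat(sprintf("<cpdag> %d nodes, %d directed, %d undirected edge(s)\n",
              length(x$nodes), nrow(x$directed), nrow(x$undirected)))
  invisible(x)
}

# ---- matrix view -----------------------------------------------------------

cpdag_matrices <- function(x) {
  p <- length(x$nodes)
  dir <- matrix(FALSE, p, p, dimnames = list(x$nodes, x$nodes))
  und <- dir
  if (nrow(x$directed) > 0L) dir[cbind(x$directed$from, x$directed$to)] <- TRUE
  if (nrow(x$undirected) > 0L) {
    und[cbind(x$undirected$from, x$undirected$to)] <- TRUE
    und[cbind(x$undirected$to, x$undirected$from)] <- TRUE
  }
  list(dir = dir, und = und)
}

matrices_to_cpdag <- function(nodes, dir, und) {
  di <- which(dir, arr.ind = TRUE)
  ui <- which(und & upper.tri(und), arr.ind = TRUE)
  cpdag(nodes,
        directed = tibble(from = nodes[di[, 1]], to = nodes[di[, 2]]),
        undirected = tibble(from = nodes[ui[, 1]], to = nodes[ui[, 2]]))
}

has_directed_cycle <- function(x) {
  p <- length(x$nodes)
  if (nrow(x$directed) == 0L) return(FALSE)
  adj <- cpdag_matrices(x)$dir
  indeg <- colSums(adj)
  alive <- rep(TRUE, p)
  repeat {
    src <- which(alive & indeg == 0)
    if (length(src) == 0L) break
    for (s in src) {
      indeg[adj[s, ]] <- indeg[adj[s, ]] - 1L
      alive[s] <- FALSE
      adj[s, ] <- FALSE
    }
  }
  any(alive)
}

#' Adjacency neighbours of a set of genes in a CPDAG
#'
#' Neighbours through directed edges in either direction and through
#' undirected edges: the relation "regulates or is regulated by".
#'
#' @param net A [cpdag()].
#' @param genes Character vector of node names (unknown names ignored).
#' @return Character vector of neighbouring node names (excluding `genes`).
#' @export
cpdag_neighbors <- function(net, genes) {
  stopifnot(inherits(net, "cpdag"))
  genes <- intersect(genes, net$nodes)
  if (length(genes) == 0L) return(character())
  nb <- c(net$directed$to[net$directed$from %in% genes],
          net$directed$from[net$directed$to %in% genes],
          net$undirected$to[net$undirected$from %in% genes],
          net$undirected$from[net$undirected$to %in% genes])
  setdiff(unique(nb), character(0))
}

# ---- consistent extension (Dor & Tarsi) ------------------------------------

# dir/und logical matrices -> DAG adjacency orienting all undirected edges,
# preserving directions and creating no new v-structure. Errors if none exists.
pdag_to_dag <- function(dir, und) {
  p <- nrow(dir)
  res <- dir
  d <- dir; u <- und
  alive <- rep(TRUE, p)
  skel <- function() d | t(d) | u
  while (any(alive)) {
    found <- FALSE
    sk <- skel()
    for (x in which(alive)) {
      if (any(d[x, alive])) next                  # x has outgoing directed edge
      nbu <- which(u[x, ] & alive)
      adjx <- which(sk[x, ] & alive)
      ok <- TRUE
      for (y in nbu) {
        others <- setdiff(adjx, y)
        if (length(others) > 0L && !all(sk[y, others])) { ok <- FALSE; break }
      }
      if (!ok) next
      res[nbu, x] <- TRUE                         # orient all y - x as y -> x
      alive[x] <- FALSE
      d[x, ] <- FALSE; d[, x] <- FALSE
      u[x, ] <- FALSE; u[, x] <- FALSE
      found <- TRUE
      break
    }
    if (!found) abort("partially directed graph admits no consistent acyclic extension")
  }
  res
}

# ---- DAG -> CPDAG (v-structures + Meek closure) ----------------------------

dag_to_cpdag_mats <- function(dag) {
  p <- nrow(dag)
  skel <- dag | t(dag)
  dir <- matrix(FALSE, p, p)
  for (y in seq_len(p)) {
    pa <- which(dag[, y])
    if (length(pa) < 2L) next
    for (i in seq_along(pa)) for (j in seq_along(pa)) {
      if (i < j && !skel[pa[i], pa[j]]) {
        dir[pa[i], y] <- TRUE
        dir[pa[j], y] <- TRUE
      }
    }
  }
  und <- skel & !(dir | t(dir))
  meek_closure(dir, und)
}

# Meek orientation rules R1-R3 applied to closure; R4 is only needed under
# background knowledge and cannot fire here.
meek_closure <- function(dir, und) {
  p <- nrow(dir)
  repeat {
    changed <- FALSE
    skel <- dir | t(dir) | und
    for (b in seq_len(p)) {
      nb_und <- which(und[b, ])
      if (length(nb_und) == 0L) next
      for (c in nb_und) {
        # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
        a_in <- which(dir[, b])
        if (any(!skel[a_in, c] & a_in != c)) {
          und[b, c] <- und[c, b] <- FALSE
          dir[b, c] <- TRUE
          changed <- TRUE
          next
        }
        # R2: b -> k -> c with b - c  =>  b -> c
        if (any(dir[b, ] & dir[, c])) {
          und[b, c] <- und[c, b] <- FALSE
          dir[b, c] <- TRUE
          changed <- TRUE
          next
        }
        # R3: b - c, b - d1, b - d2, d1 -> c, d2 -> c, d1,d2 non-adjacent => b -> c
        ds <- which(und[b, ] & dir[, c])
        if (length(ds) >= 2L) {
          hit <- FALSE
          for (i in seq_along(ds)) for (j in seq_along(ds)) {
            if (i < j && !skel[ds[i], ds[j]]) hit <- TRUE
          }
          if (hit) {
            und[b, c] <- und[c, b] <- FALSE
            dir[b, c] <- TRUE
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  list(dir = dir, und = und)
}
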