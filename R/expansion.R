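#' One-step pathway expansion through a gene network
#'
#' Adds to each gene set every network neighbour of its members: gene J joins
#' a pathway if it regulates, or is regulated by, some member gene I in the
#' network. Undirected CPDAG edges count in both directions, since they mark
#' orientations the data cannot determine and the rule is adjacency-based.
#' Network nodes outside the collection's universe are ignored with a warning.
#'
#' @param gene_sets A [gene_set_collection()].
#' @param net A [cpdag()].
#' @return A `gene_set_collection` over the same universe with each set
#'   unioned with its members' neighbours.
#' @export
expand_once <- function(gene_sets, net) {
  stopifnot(inherits(gene_sets, "gene_set_collection"), inherits(net, "cpdag"))
  universe <- set_universe(gene_sets)
  outside <- setdiff(net$nodes, universe)
  if (length(outside) > 0L) {
    warn(sprintf("ignoring %d network node(s) outside the universe", length(outside)))
  }
  expanded <- lapply(set_list(gene_sets), function(g) {
    union(g, intersect(cpdag_neighbors(net, g), universe))
  })
  gene_set_collection(expanded, universe,
                      descriptions = setNames(gene_sets$description,
                                              gene_sets$set_name))
}

#' Build the full family of expanded pathway collections
#'
#' Repeats [expand_once()] up to `max_steps` times with each of the two
#' condition-specific networks, yielding `1 + 2 * max_steps` collections: the
#' raw sets plus one per (condition, step). With the default `max_steps = 3`
#' that is 7 collections. Step-k sets equal the k-neighbourhood ball of the
#' raw sets in the network's adjacency graph, so growth is monotone and
#' saturates at connected components.
#'
#' @param gene_sets A [gene_set_collection()] (the raw sets).
#' @param net_group1,net_group2 [cpdag()] networks learned from group1 and
#'   group2 samples.
#' @param max_steps Number of expansion rounds per condition (default 3).
#' @return An object of class `expansion_result`: list with `collections`
#'   (named list of collections, keys `"raw"`, `"group1_1"`, ...,
#'   `"group2_<max_steps>"`) and `provenance` (tibble `collection`,
#'   `condition`, `steps`, `set_name`, `gene`, `step_added`).
#' @export
build_expansion <- function(gene_sets, net_group1, net_group2, max_steps = 3) {
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  if (max_steps < 1L) abort("max_steps must be >= 1")
  collections <- list(raw = gene_sets)
  prov <- list(provenance_tbl(gene_sets, "raw", "raw", 0L, set_list(gene_sets)))
  for (cond in c("group1", "group2")) {
    net <- if (cond == "group1") net_group1 else net_group2
    stopifnot(inherits(net, "cpdag"))
    cur <- gene_sets
    prev_members <- set_list(gene_sets)
    for (k in seq_len(max_steps)) {
      cur <- expand_once(cur, net)
      key <- paste0(cond, "_", k)
      collections[[key]] <- cur
      added <- purrr::map2(set_list(cur), prev_members[names(set_list(cur))],
                           setdiff)
      prov[[length(prov) + 1L]] <- provenance_tbl(cur, key, cond, k, added)
      prev_members <- set_list(cur)
    }
  }
  structure(list(collections = collections,
                 provenance = dplyr::bind_rows(prov)),
            max_steps = max_steps,
            class = "expansion_result")
}

provenance_tbl <- function(coll, key, cond, step, added) {
  rows <- purrr::imap(added, function(genes, set_name) {
    if (length(genes) == 0L) return(NULL)
    tibble(collection = key, condition = cond, steps = step,
           set_name = set_name, gene = genes, step_added = step)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf("<expansion_result> %d collections (max_steps = %d)\n",
              length(x$collections), attr(x, "max_steps")))
  invisible(x)
}

#' Re-test pathway activation on every expanded collection
#'
#' Applies [classify_pathways()] to each collection of an
#' [build_expansion()] result using the same gene classes and universe, so
#' differences between collections reflect the networks alone. Expansion
#' inflates pathway membership, and with it significance; reports downstream
#' default to the one-step collections for that reason.
#'
#' @param expansion An `expansion_result`.
#' @param gene_classes Output of [classify_genes()].
#' @param alpha Per-tail threshold.
#' @return Tibble of pathway classifications with columns `collection`,
#'   `condition`, `steps` prepended.
#' @export
classify_expanded <- function(expansion, gene_classes, alpha = 0.05) {
  stopifnot(inherits(expansion, "expansion_result"))
  purrr::imap_dfr(expansion$collections, function(coll, key) {
    res <- classify_pathways(gene_classes, coll, alpha = alpha)
    cond <- if (key == "raw") "raw" else sub("_[0-9]+$", "", key)
    steps <- if (key == "raw") 0L else as.integer(sub("^.*_", "", key))
    dplyr::bind_cols(tibble(collection = key, condition = cond, steps = steps),
                     res)
  })
}
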