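#' Build the pathway-crosstalk network
#'
#' Nodes are the pathways significant in either direction of the Step-2 test;
#' every unordered pair of them is tested for gene-membership overlap by
#' [overlap_pvalue()] with `nall` the size of the union of all pathway gene
#' sets in the collection. The multiple-testing family is exactly the pairs
#' tested (significant pathways only); Benjamini-Hochberg q-values are
#' computed over it and edges with `q < fdr_threshold` are retained.
#'
#' @param pathway_classes Output of [classify_pathways()] computed on the
#'   same collection.
#' @param gene_sets The [gene_set_collection()] the classes were computed on.
#' @param fdr_threshold Edge retention threshold on q (default 0.05).
#' @param variant Overlap p-value variant, see [overlap_pvalue()].
#' @return An object of class `pathway_network`: list with `nodes` (tibble
#'   `pathway`, `class`, `size`, `p_g1`, `p_g2`), `edges` (tibble
#'   `pathway_a`, `pathway_b`, `na`, `nb`, `nab`, `nall`, `p`, `q`) holding
#'   the retained edges, and `all_pairs` (every tested pair).
#' @export
build_pathway_network <- function(pathway_classes, gene_sets,
                                  fdr_threshold = 0.05,
                                  variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  sets <- set_list(gene_sets)
  nall <- length(unique(unlist(sets)))
  sig <- pathway_classes[pathway_classes$significant_g1 |
                           pathway_classes$significant_g2, , drop = FALSE]
  sig <- sig[sig$pathway %in% names(sets), , drop = FALSE]
  nodes <- tibble(pathway = sig$pathway,
                  class = sig$class,
                  size = lengths(sets[sig$pathway]),
                  p_g1 = sig$p_g1, p_g2 = sig$p_g2)
  empty_edges <- tibble(pathway_a = character(), pathway_b = character(),
                        na = integer(), nb = integer(), nab = integer(),
                        nall = integer(), p = double(), q = double())
  if (nrow(nodes) < 2L) {
    warn("fewer than 2 significant pathways: empty crosstalk network")
    return(new_pathway_network(nodes, empty_edges, empty_edges,
                               fdr_threshold, variant))
  }
  pairs <- t(combn(sort(nodes$pathway), 2L))
  pair_tbl <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    ga <- sets[[a]]; gb <- sets[[b]]
    tibble(pathway_a = a, pathway_b = b,
           na = length(ga), nb = length(gb),
           nab = length(intersect(ga, gb)), nall = nall)
  })
  pair_tbl$p <- overlap_pvalue(pair_tbl$na, pair_tbl$nb, pair_tbl$nab,
                               pair_tbl$nall, variant = variant)
  pair_tbl$q <- bh_fdr(pair_tbl$p)
  edges <- pair_tbl[pair_tbl$q < fdr_threshold, , drop = FALSE]
  new_pathway_network(nodes, edges, pair_tbl, fdr_threshold, variant)
}

new_pathway_network <- function(nodes, edges, all_pairs, threshold, variant) {
  structure(list(nodes = nodes, edges = edges, all_pairs = all_pairs),
            fdr_threshold = threshold, variant = variant,
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("<pathway_network> %d significant pathway(s), %d edge(s) at q < %g\n",
              nrow(x$nodes), nrow(x$edges), attr(x, "fdr_threshold")))
  invisible(x)
}

edge_keys <- function(edges) {
  paste(pmin(edges$pathway_a, edges$pathway_b),
        pmax(edges$pathway_a, edges$pathway_b), sep = "||")
}

#' Compare two pathway networks
#'
#' Set algebra on unordered edge keys: edges common to both networks, edges
#' specific to each, and per-network hub reports (nodes ranked by degree
#' within the specific edges -- the pathways that organise each condition's
#' private crosstalk).
#'
#' @param net_a,net_b `pathway_network` objects over the same pathway
#'   universe.
#' @return List of class `network_comparison`: `common`, `a_specific`,
#'   `b_specific` (edge tibbles) and `hubs` (tibble `network`, `pathway`,
#'   `degree`).
#' @export
compare_networks <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "pathway_network"),
            inherits(net_b, "pathway_network"))
  ka <- edge_keys(net_a$edges)
  kb <- edge_keys(net_b$edges)
  common <- net_a$edges[ka %in% kb, , drop = FALSE]
  a_spec <- net_a$edges[!ka %in% kb, , drop = FALSE]
  b_spec <- net_b$edges[!kb %in% ka, , drop = FALSE]
  hub_tbl <- function(edges, label) {
    if (nrow(edges) == 0L) {
      return(tibble(network = character(), pathway = character(),
                    degree = integer()))
    }
    deg <- sort(table(c(edges$pathway_a, edges$pathway_b)), decreasing = TRUE)
    tibble(network = label, pathway = names(deg), degree = as.integer(deg))
  }
  structure(list(common = common, a_specific = a_spec, b_specific = b_spec,
                 hubs = dplyr::bind_rows(hub_tbl(a_spec, "a"),
                                         hub_tbl(b_spec, "b"))),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("<network_comparison> common %d | a-specific %d | b-specific %d\n",
              nrow(x$common), nrow(x$a_specific), nrow(x$b_specific)))
  invisible(x)
}
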