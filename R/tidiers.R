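# broom-style accessors for the package's result objects.

#' @export
tidy.cpdag <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$directed, type = "directed"),
    dplyr::mutate(x$undirected, type = "undirected"))
}

#' @export
glance.cpdag <- function(x, ...) {
  tibble(n_nodes = length(x$nodes),
         n_directed = nrow(x$directed),
         n_undirected = nrow(x$undirected),
         score = attr(x, "score") %||% NA_real_,
         penalty_discount = attr(x, "penalty_discount") %||% NA_real_,
         n_samples = attr(x, "n") %||% NA_integer_)
}

#' @export
tidy.pathway_network <- function(x, ...) as_tibble(x$edges)

#' @export
glance.pathway_network <- function(x, ...) {
  tibble(n_pathways = nrow(x$nodes),
         n_edges = nrow(x$edges),
         n_pairs_tested = nrow(x$all_pairs),
         fdr_threshold = attr(x, "fdr_threshold"),
         variant = attr(x, "variant"))
}

#' @export
tidy.robustness_summary <- function(x, ...) as_tibble(x$iterations)

#' @export
glance.robustness_summary <- function(x, ...) {
  dplyr::bind_cols(tibble(n_iterations = attr(x, "n_iter"),
                          subsample_size = attr(x, "subsample_size")),
                   x$means)
}

#' @export
tidy.expansion_result <- function(x, ...) as_tibble(x$provenance)

#' @export
glance.expansion_result <- function(x, ...) {
  purrr::imap_dfr(x$collections, function(coll, key) {
    tibble(collection = key,
           n_sets = nrow(coll),
           mean_size = mean(lengths(coll$genes)),
           total_genes = length(unique(unlist(coll$genes))))
  })
}

#' @export
tidy.gene_classification <- function(x, ...) as_tibble(unclass_tbl(x))

#' @export
glance.gene_classification <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_group1_active = sum(x$class == "GROUP1_ACTIVE"),
         n_group2_active = sum(x$class == "GROUP2_ACTIVE"),
         n_ns = sum(x$class == "NS"),
         alpha = attr(x, "alpha"))
}

#' @export
tidy.pathway_classification <- function(x, ...) as_tibble(unclass_tbl(x))

#' @export
glance.pathway_classification <- function(x, ...) {
  tibble(n_pathways = nrow(x),
         n_group1 = sum(x$significant_g1),
         n_group2 = sum(x$significant_g2),
         n_both = sum(x$significant_g1 & x$significant_g2),
         alpha = attr(x, "alpha"))
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("gene_classification",
                                  "pathway_classification"))
  x
}
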