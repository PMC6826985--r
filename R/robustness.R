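#' Group-imbalance robustness analysis
#'
#' When one group is much larger than the other, the per-gene tests gain
#' power asymmetrically. This analysis repeatedly subsamples the larger group
#' down to `subsample_size` (without replacement; the smaller group is kept
#' whole), reruns the gene and pathway classification, and summarises how
#' stable the calls are: per-class gene counts, the overlap of subsample
#' calls with the full-data calls (same direction), the analogous pathway
#' quantities, and the Pearson correlation between the subsample's and the
#' full run's pathway score vectors, taken as -log10 p per direction -- the
#' only per-pathway continuous quantity the method produces.
#'
#' @param activity An activity table.
#' @param groups A [sample_groups()] annotation.
#' @param gene_sets A [gene_set_collection()].
#' @param n_iter Number of subsampling iterations (default 10).
#' @param subsample_size Samples drawn from the larger group; defaults to the
#'   size of the smaller group (balanced design).
#' @param alpha Per-tail threshold for both classification steps.
#' @param seed Integer seed; the whole analysis is deterministic given it.
#' @return Object of class `robustness_summary`: list with `iterations`
#'   (per-iteration tibble) and `means` (one-row tibble of across-iteration
#'   means).
#' @export
run_robustness <- function(activity, groups, gene_sets, n_iter = 10,
                           subsample_size = NULL, alpha = 0.05, seed = 1) {
  sizes <- c(length(group_members(groups, "group1")),
             length(group_members(groups, "group2")))
  big <- which.max(sizes)
  small <- 3L - big
  roles <- c("group1", "group2")
  if (is.null(subsample_size)) subsample_size <- sizes[small]
  if (subsample_size > sizes[big]) {
    abort("subsample_size exceeds the larger group's size")
  }

  full_counts <- activity_counts(activity, groups)
  full_genes <- classify_genes(full_counts, alpha = alpha)
  full_paths <- classify_pathways(full_genes, gene_sets, alpha = alpha)

  big_ids <- group_members(groups, roles[big])
  small_ids <- group_members(groups, roles[small])

  iterations <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_iter), function(it) {
      take <- sample(big_ids, subsample_size, replace = FALSE)
      keep <- c(take, small_ids)
      sub_groups <- sample_groups(
        tibble(sample_id = groups$sample_id, group = groups$group) |>
          dplyr::filter(.data$sample_id %in% keep),
        group1 = group_labels(groups)[["group1"]])
      sub_act <- activity[c("gene", intersect(names(activity)[-1L], keep))]
      sub_genes <- classify_genes(activity_counts(sub_act, sub_groups),
                                  alpha = alpha)
      sub_paths <- classify_pathways(sub_genes, gene_sets, alpha = alpha)
      summarise_iteration(it, sub_genes, sub_paths, full_genes, full_paths)
    })
  })
  means <- dplyr::summarise(iterations,
                            dplyr::across(-"iteration", ~ mean(.x, na.rm = TRUE)))
  structure(list(iterations = iterations, means = means,
                 full_genes = full_genes, full_paths = full_paths),
            n_iter = n_iter, subsample_size = subsample_size, seed = seed,
            class = "robustness_summary")
}

overlap_stat <- function(sub_ids, full_ids) {
  n_sub <- length(sub_ids)
  n_ov <- length(intersect(sub_ids, full_ids))
  c(n = n_sub, overlap = n_ov)
}

# correlation of -log10 p vectors, with the exact-identity case pinned to 1
# (a constant vector has no variance, but identical runs are perfectly stable)
safe_cor <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  if (isTRUE(all.equal(x, y))) return(1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y)
}

summarise_iteration <- function(it, sub_genes, sub_paths, full_genes, full_paths) {
  g1_sub <- sub_genes$gene[sub_genes$class == "GROUP1_ACTIVE"]
  g2_sub <- sub_genes$gene[sub_genes$class == "GROUP2_ACTIVE"]
  g1_full <- full_genes$gene[full_genes$class == "GROUP1_ACTIVE"]
  g2_full <- full_genes$gene[full_genes$class == "GROUP2_ACTIVE"]
  sg1 <- overlap_stat(g1_sub, g1_full)
  sg2 <- overlap_stat(g2_sub, g2_full)

  p1_sub <- sub_paths$pathway[sub_paths$significant_g1]
  p2_sub <- sub_paths$pathway[sub_paths$significant_g2]
  p1_full <- full_paths$pathway[full_paths$significant_g1]
  p2_full <- full_paths$pathway[full_paths$significant_g2]
  sp1 <- overlap_stat(p1_sub, p1_full)
  sp2 <- overlap_stat(p2_sub, p2_full)

  shared <- intersect(sub_paths$pathway, full_paths$pathway)
  i_sub <- match(shared, sub_paths$pathway)
  i_full <- match(shared, full_paths$pathway)
  cor_g1 <- safe_cor(-log10(sub_paths$p_g1[i_sub]),
                     -log10(full_paths$p_g1[i_full]))
  cor_g2 <- safe_cor(-log10(sub_paths$p_g2[i_sub]),
                     -log10(full_paths$p_g2[i_full]))

  prop <- function(ov, n) if (n == 0) NA_real_ else ov / n
  tibble(iteration = it,
         genes_g1 = sg1[["n"]], genes_g2 = sg2[["n"]],
         gene_overlap = sg1[["overlap"]] + sg2[["overlap"]],
         gene_overlap_prop = prop(sg1[["overlap"]] + sg2[["overlap"]],
                                  sg1[["n"]] + sg2[["n"]]),
         pathways_g1 = sp1[["n"]], pathways_g2 = sp2[["n"]],
         pathway_overlap = sp1[["overlap"]] + sp2[["overlap"]],
         pathway_overlap_prop = prop(sp1[["overlap"]] + sp2[["overlap"]],
                                     sp1[["n"]] + sp2[["n"]]),
         cor_g1 = cor_g1, cor_g2 = cor_g2)
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat(sprintf("<robustness_summary> %d iteration(s), subsample size %d\n",
              attr(x, "n_iter"), attr(x, "subsample_size")))
  print(x$means)
  invisible(x)
}
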