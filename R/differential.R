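#' Classify genes as differentially active between two groups
#'
#' Step 1 of the two-step method. For each gene with group activity counts
#' `(n11, n12, n21, n22)`, two one-tailed Fisher exact tests compare the
#' active-sample proportions p1 = n11/(n11+n12) and p2 = n21/(n21+n22):
#' `p_left` tests H1: p1 > p2 (the gene is more active in group1) and
#' `p_right` tests H1: p1 < p2. Genes fall into three mutually exclusive
#' classes at threshold `alpha`: `GROUP1_ACTIVE` (p_left < alpha),
#' `GROUP2_ACTIVE` (p_right < alpha), otherwise `NS`. Since
#' p_left + p_right >= 1 (both tails include the observed table), the two
#' significant classes cannot co-occur for alpha <= 0.5.
#'
#' No multiple-testing correction is applied at this stage by default; the
#' method's downstream pathway stage consumes the raw-threshold classes.
#' Set `fdr = TRUE` to classify on BH-adjusted tails instead.
#'
#' @param counts A tibble from [activity_counts()].
#' @param alpha Per-tail significance threshold (default 0.05).
#' @param fdr Adjust each tail by Benjamini-Hochberg before thresholding.
#' @return The counts tibble with added columns `p_left`, `p_right`, `class`.
#' @export
classify_genes <- function(counts, alpha = 0.05, fdr = FALSE) {
  need <- c("gene", "n11", "n12", "n21", "n22")
  if (!all(need %in% names(counts))) {
    abort("`counts` must have columns gene, n11, n12, n21, n22")
  }
  if (nrow(counts) == 0L) abort("empty counts table")
  if (length(unique(counts$n11 + counts$n12)) != 1L ||
      length(unique(counts$n21 + counts$n22)) != 1L) {
    abort("rows disagree on group sizes; counts table is inconsistent")
  }
  p_left <- fisher_one_tailed(counts$n11, counts$n12, counts$n21, counts$n22,
                              "greater_first_cell")
  p_right <- fisher_one_tailed(counts$n11, counts$n12, counts$n21, counts$n22,
                               "less_first_cell")
  pl <- if (fdr) bh_fdr(p_left) else p_left
  pr <- if (fdr) bh_fdr(p_right) else p_right
  cls <- dplyr::case_when(pl < alpha ~ "GROUP1_ACTIVE",
                          pr < alpha ~ "GROUP2_ACTIVE",
                          TRUE ~ "NS")
  out <- as_tibble(counts)
  out$p_left <- p_left
  out$p_right <- p_right
  out$class <- cls
  structure(out, alpha = alpha, class = c("gene_classification", class(out)))
}

#' Classify pathways as differentially active
#'
#' Step 2 of the two-step method. With `Np` group1-active and `Nm`
#' group2-active genes among the `N` genes of the universe, each pathway of
#' `m` member genes (of which `mp` are group1-active and `mm` group2-active)
#' is tested twice by one-tailed Fisher exact tests: `p_g1` asks whether the
#' proportion of group1-active genes inside the pathway exceeds the proportion
#' outside (table `[[mp, m-mp], [Np-mp, (N-m)-(Np-mp)]]`, greater tail), and
#' `p_g2` analogously for group2-active genes. A pathway can be significant in
#' both directions simultaneously; such pathways are the prime candidates for
#' alternative activation.
#'
#' @param gene_classes Output of [classify_genes()].
#' @param gene_sets A [gene_set_collection()]. Members outside the universe
#'   were already removed at construction; members absent from `gene_classes`
#'   are ignored for `mp`/`mm`.
#' @param alpha Per-tail significance threshold (default 0.05).
#' @param universe Optional explicit background gene vector; defaults to the
#'   collection's universe intersected with the classified genes.
#' @return A tibble with one row per pathway: `pathway`, `m`, `mp`, `mm`,
#'   `p_g1`, `p_g2`, `significant_g1`, `significant_g2`, `class`
#'   (`group1` / `group2` / `both` / `NS`).
#' @export
classify_pathways <- function(gene_classes, gene_sets, alpha = 0.05,
                              universe = NULL) {
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  if (!all(c("gene", "class") %in% names(gene_classes))) {
    abort("`gene_classes` must have columns gene and class")
  }
  if (is.null(universe)) {
    universe <- intersect(set_universe(gene_sets), gene_classes$gene)
  }
  cls <- gene_classes$class[match(universe, gene_classes$gene)]
  g1_active <- universe[!is.na(cls) & cls == "GROUP1_ACTIVE"]
  g2_active <- universe[!is.na(cls) & cls == "GROUP2_ACTIVE"]
  N <- length(universe)
  Np <- length(g1_active)
  Nm <- length(g2_active)

  members <- lapply(set_list(gene_sets), intersect, universe)
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warn(sprintf("skipping %d pathway(s) with no measured members", sum(empty)))
    members <- members[!empty]
  }
  m <- unname(lengths(members))
  mp <- vapply(members, function(g) length(intersect(g, g1_active)),
               integer(1), USE.NAMES = FALSE)
  mm <- vapply(members, function(g) length(intersect(g, g2_active)),
               integer(1), USE.NAMES = FALSE)
  p_g1 <- fisher_one_tailed(mp, m - mp, Np - mp, (N - m) - (Np - mp),
                            "greater_first_cell")
  p_g2 <- fisher_one_tailed(mm, m - mm, Nm - mm, (N - m) - (Nm - mm),
                            "greater_first_cell")
  sig1 <- p_g1 < alpha
  sig2 <- p_g2 < alpha
  out <- tibble(pathway = names(members),
                m = as.integer(m), mp = mp, mm = mm,
                Np = Np, Nm = Nm, N = N,
                p_g1 = p_g1, p_g2 = p_g2,
                significant_g1 = sig1, significant_g2 = sig2,
                class = dplyr::case_when(sig1 & sig2 ~ "both",
                                         sig1 ~ "group1",
                                         sig2 ~ "group2",
                                         TRUE ~ "NS"))
  structure(out, alpha = alpha,
            class = c("pathway_classification", class(out)))
}
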