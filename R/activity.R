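#' Collapse probe-level detection calls to gene-level binary activity
#'
#' A gene is active in a sample if at least one of its probes carries a
#' Present (P) call in that sample; Marginal (M) and Absent (A) both count as
#' inactive. Probes absent from the probe-gene map are dropped (logged), and a
#' gene with zero mapped probes never appears in the output.
#'
#' @param pma A PMA call table: tibble with first column `probe_id` and one
#'   character column per sample with values in `P`/`M`/`A`
#'   (see [read_pma_table()]).
#' @param probe_map A data frame with columns `probe_id`, `gene`.
#' @param groups A [sample_groups()] annotation covering every sample column.
#' @return An activity table: tibble with first column `gene` and one
#'   integer 0/1 column per sample, rows sorted by gene.
#' @examples
#' pma <- tibble::tibble(probe_id = c("p1", "p2"),
#'                       s1 = c("P", "A"), s2 = c("M", "A"))
#' map <- tibble::tibble(probe_id = c("p1", "p2"), gene = c("G1", "G1"))
#' sg <- sample_groups(data.frame(sample_id = c("s1", "s2"),
#'                                group = c("a", "b")), group1 = "a")
#' probes_to_gene_activity(pma, map, sg)
#' @export
probes_to_gene_activity <- function(pma, probe_map, groups) {
  stopifnot(is.data.frame(pma), is.data.frame(probe_map))
  if (names(pma)[1L] != "probe_id") abort("first column of `pma` must be `probe_id`")
  sample_ids <- names(pma)[-1L]
  check_samples_labelled(sample_ids, groups)
  if (anyDuplicated(probe_map$probe_id)) abort("duplicated probe ids in probe map")

  keep <- pma$probe_id %in% probe_map$probe_id
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    inform(sprintf("dropping %d probe(s) absent from the probe map", n_drop))
  }
  if (!any(keep)) abort("no probe in the PMA table maps to a gene")
  pma <- pma[keep, , drop = FALSE]
  gene <- probe_map$gene[match(pma$probe_id, probe_map$probe_id)]

  present <- vapply(pma[sample_ids],
                    function(col) toupper(col) == "P",
                    logical(nrow(pma)))
  present <- matrix(present, nrow = nrow(pma),
                    dimnames = list(NULL, sample_ids))
  # OR over probes of the same gene
  act <- rowsum(present + 0L, group = gene) > 0L
  act <- act[order(rownames(act)), , drop = FALSE]
  dplyr::bind_cols(tibble(gene = rownames(act)),
                   as_tibble(act + 0L))
}

#' Per-gene two-group activity counts
#'
#' For each gene, counts active/inactive samples per group: `n11` and `n12`
#' are the active and inactive sample counts in group1, `n21` and `n22` in
#' group2. Rows always satisfy `n11 + n12 = |group1|` and
#' `n21 + n22 = |group2|`.
#'
#' @param activity An activity table (first column `gene`, then 0/1 sample
#'   columns).
#' @param groups A [sample_groups()] annotation.
#' @return A tibble with columns `gene`, `n11`, `n12`, `n21`, `n22`.
#' @export
activity_counts <- function(activity, groups) {
  m <- act_matrix(activity)
  check_samples_labelled(colnames(m), groups)
  g1 <- intersect(colnames(m), group_members(groups, "group1"))
  g2 <- intersect(colnames(m), group_members(groups, "group2"))
  if (length(g1) == 0L || length(g2) == 0L) {
    abort("both groups must have at least one sample in the activity table")
  }
  n11 <- rowSums(m[, g1, drop = FALSE])
  n21 <- rowSums(m[, g2, drop = FALSE])
  tibble(gene = rownames(m),
         n11 = as.integer(n11),
         n12 = length(g1) - as.integer(n11),
         n21 = as.integer(n21),
         n22 = length(g2) - as.integer(n21))
}

#' Restrict an activity table to one group's samples
#'
#' @param activity An activity table.
#' @param groups A [sample_groups()] annotation.
#' @param role `"group1"` or `"group2"`.
#' @return An activity table containing only that group's sample columns.
#' @export
activity_group <- function(activity, groups, role = c("group1", "group2")) {
  role <- match.arg(role)
  keep <- intersect(names(activity)[-1L], group_members(groups, role))
  if (length(keep) == 0L) abort(sprintf("no %s samples in activity table", role))
  activity[c("gene", keep)]
}

# internal: activity tibble -> 0/1 matrix, genes in rownames
act_matrix <- function(activity) {
  stopifnot(is.data.frame(activity))
  if (names(activity)[1L] != "gene") abort("first column must be `gene`")
  m <- as.matrix(activity[-1L])
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m != 0L & m != 1L)) abort("activity values must be 0/1")
  rownames(m) <- activity$gene
  m
}
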