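JOINT_STATES <- c("00", "01", "10", "11")

# pattern type of an ordered transition: 2 = one gene's bit changes,
# 3 = both change concordantly (00<->11), 4 = both change inversely (01<->10)
transition_type <- function(from, to) {
  bits_from <- strsplit(from, "")[[1]]
  bits_to <- strsplit(to, "")[[1]]
  diff <- sum(bits_from != bits_to)
  if (diff == 0L) abort("from and to states must differ")
  if (diff == 1L) return(2L)
  if (bits_from[1] == bits_from[2]) 3L else 4L
}

#' Joint activity-state counts for a gene pair
#'
#' For a pair (A, B) each sample is in one of four joint states, written as
#' two bits with A's activity first: `00`, `01`, `10`, `11`. Counts are
#' tallied separately per group; within each group they sum to the group size.
#'
#' @param activity An activity table.
#' @param groups A [sample_groups()] annotation.
#' @param gene_a,gene_b Gene symbols present in `activity`.
#' @return A tibble of class `pair_state_counts` with columns `role`
#'   (`group1`/`group2`), `state`, `n` (all 8 combinations present).
#' @export
pair_state_counts <- function(activity, groups, gene_a, gene_b) {
  m <- act_matrix(activity)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(m)) abort(sprintf("gene '%s' not in activity table", g))
  }
  check_samples_labelled(colnames(m), groups)
  state <- paste0(m[gene_a, ], m[gene_b, ])
  role <- ifelse(colnames(m) %in% group_members(groups, "group1"),
                 "group1", "group2")
  tab <- table(factor(role, levels = c("group1", "group2")),
               factor(state, levels = JOINT_STATES))
  out <- as_tibble(tab, .name_repair = "minimal")
  names(out) <- c("role", "state", "n")
  out$n <- as.integer(out$n)
  out <- dplyr::arrange(out, .data$role, .data$state)
  structure(out, gene_a = gene_a, gene_b = gene_b,
            class = c("pair_state_counts", class(out)))
}

# internal: counts tibble -> 2x4 matrix (rows group1/group2)
psc_matrix <- function(counts) {
  stopifnot(all(c("role", "state", "n") %in% names(counts)))
  m <- matrix(0L, 2, 4, dimnames = list(c("group1", "group2"), JOINT_STATES))
  m[cbind(counts$role, counts$state)] <- counts$n
  m
}

#' Test one state transition for a gene pair
#'
#' Tests whether samples shift from joint state `from` to joint state `to`
#' between group1 and group2. Conditioning on the samples that are in either
#' of the two states, the 2x2 table is
#' `[[c1[from], c1[to]], [c2[from], c2[to]]]` and the greater tail on the
#' first cell asks whether the from-state is over-represented in group1
#' relative to group2 -- evidence that the pair moved from `from` to `to` as
#' group1 turns into group2. If no sample of either group occupies the two
#' states, p = 1.
#'
#' @param counts A [pair_state_counts()] tibble.
#' @param from,to Distinct joint states among `"00"`, `"01"`, `"10"`, `"11"`.
#' @param alpha Significance threshold recorded in the result.
#' @return One-row tibble: `from`, `to`, `pattern_type` (2, 3 or 4),
#'   `p_value`, `significant`.
#' @export
test_transition <- function(counts, from, to, alpha = 0.05) {
  from <- match.arg(from, JOINT_STATES)
  to <- match.arg(to, JOINT_STATES)
  m <- psc_matrix(counts)
  p <- fisher_one_tailed(m["group1", from], m["group1", to],
                         m["group2", from], m["group2", to],
                         "greater_first_cell")
  tibble(from = from, to = to,
         pattern_type = transition_type(from, to),
         p_value = p, significant = p < alpha)
}

#' Assign the regulated alteration pattern of a gene pair
#'
#' Gene pairs whose members show no differential activity individually are
#' assigned Pattern 1 (no change) without testing, unless `gate = FALSE`.
#' Otherwise all 12 ordered transitions between distinct joint states are
#' tested; among those significant at `alpha` the transition with the minimal
#' p-value is the assigned pattern (ties broken lexicographically on
#' `(from, to)`). If none is significant the pair falls back to Pattern 1.
#'
#' @param counts A [pair_state_counts()] tibble.
#' @param class_a,class_b Step-1 classes of the two genes
#'   (`GROUP1_ACTIVE` / `GROUP2_ACTIVE` / `NS`).
#' @param alpha Significance threshold (default 0.05).
#' @param gate If `TRUE` (default) require at least one non-NS gene before
#'   testing.
#' @return One-row tibble: `gene_a`, `gene_b`, `assigned` (`"PATTERN1"` or
#'   `"XY->ZW"`), `pattern_type` (1-4), `min_p` (NA for Pattern 1),
#'   `n_significant`, `significant_transitions` (comma-joined), `tested`.
#' @export
assign_pattern <- function(counts, class_a = "NS", class_b = "NS",
                           alpha = 0.05, gate = TRUE) {
  ga <- attr(counts, "gene_a") %||% NA_character_
  gb <- attr(counts, "gene_b") %||% NA_character_
  base <- tibble(gene_a = ga, gene_b = gb, assigned = "PATTERN1",
                 pattern_type = 1L, min_p = NA_real_, n_significant = 0L,
                 significant_transitions = "", tested = FALSE)
  if (gate && class_a == "NS" && class_b == "NS") return(base)

  trans <- transition_table(counts, alpha)
  base$tested <- TRUE
  sig <- trans[trans$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(base)
  sig <- dplyr::arrange(sig, .data$p_value, .data$from, .data$to)
  base$assigned <- paste0(sig$from[1], "->", sig$to[1])
  base$pattern_type <- sig$pattern_type[1]
  base$min_p <- sig$p_value[1]
  base$n_significant <- nrow(sig)
  base$significant_transitions <-
    paste(paste0(sig$from, "->", sig$to), collapse = ",")
  base
}

#' All 12 ordered transition tests for a gene pair
#' @inheritParams test_transition
#' @return Tibble with one row per ordered transition.
#' @export
transition_table <- function(counts, alpha = 0.05) {
  grid <- expand.grid(from = JOINT_STATES, to = JOINT_STATES,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, , drop = FALSE]
  purrr::pmap_dfr(grid, function(from, to) {
    test_transition(counts, from, to, alpha)
  })
}

#' Scan a list of gene pairs for alteration patterns
#'
#' Applies [assign_pattern()] to every pair in a pathway edge list (for
#' example the cytokine-receptor edges of a signalling pathway). Pairs with a
#' gene missing from the activity table are skipped with a warning. The
#' report is sorted by `min_p`.
#'
#' @param activity An activity table.
#' @param pairs A data frame with columns `gene_a`, `gene_b` and optionally
#'   `pathway`.
#' @param groups A [sample_groups()] annotation.
#' @param gene_classes Output of [classify_genes()].
#' @param alpha Significance threshold.
#' @param gate Pass `FALSE` to test pairs regardless of their Step-1 classes.
#' @return Tibble of pattern assignments (possibly zero rows).
#' @export
pattern_scan <- function(activity, pairs, groups, gene_classes,
                         alpha = 0.05, gate = TRUE) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("gene_a", "gene_b") %in% names(pairs))) {
    abort("`pairs` must have columns gene_a and gene_b")
  }
  empty <- tibble(gene_a = character(), gene_b = character(),
                  assigned = character(), pattern_type = integer(),
                  min_p = double(), n_significant = integer(),
                  significant_transitions = character(), tested = logical())
  if (nrow(pairs) == 0L) return(empty)
  measured <- activity$gene
  ok <- pairs$gene_a %in% measured & pairs$gene_b %in% measured
  if (any(!ok)) {
    warn(sprintf("skipping %d pair(s) with unmeasured genes", sum(!ok)))
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) return(empty)
  cls <- setNames(gene_classes$class, gene_classes$gene)
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    psc <- pair_state_counts(activity, groups, a, b)
    row <- assign_pattern(psc,
                          class_a = cls[[a]] %||% "NS",
                          class_b = cls[[b]] %||% "NS",
                          alpha = alpha, gate = gate)
    if ("pathway" %in% names(pairs)) row$pathway <- pairs$pathway[i]
    row
  })
  dplyr::arrange(out, .data$min_p)
}

#' Node-level alternative-activation report
#'
#' Pathway-diagram nodes often stand for several interchangeable genes (a
#' calmodulin node may represent CALM1..CALML6). For each (pathway, node) the
#' report lists which member genes are group1-active and which are
#' group2-active; nodes with active members in both groups are flagged
#' `ALTERNATIVE` -- the same node is used under both conditions but through
#' different genes.
#'
#' @param node_map A data frame with columns `pathway`, `node`, `gene`.
#' @param gene_classes Output of [classify_genes()].
#' @return Tibble: `pathway`, `node`, `n_members`, `group1_active`,
#'   `group2_active` (comma-joined symbols), `n_group1`, `n_group2`,
#'   `alternative`.
#' @export
node_activity_report <- function(node_map, gene_classes) {
  stopifnot(is.data.frame(node_map))
  if (!all(c("pathway", "node", "gene") %in% names(node_map))) {
    abort("`node_map` must have columns pathway, node, gene")
  }
  cls <- setNames(gene_classes$class, gene_classes$gene)
  node_map |>
    dplyr::filter(.data$gene %in% names(cls)) |>
    dplyr::group_by(.data$pathway, .data$node) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      group1_active = paste(sort(.data$gene[cls[.data$gene] == "GROUP1_ACTIVE"]),
                            collapse = ","),
      group2_active = paste(sort(.data$gene[cls[.data$gene] == "GROUP2_ACTIVE"]),
                            collapse = ","),
      .groups = "drop") |>
    dplyr::mutate(
      n_group1 = ifelse(.data$group1_active == "", 0L,
                        stringr::str_count(.data$group1_active, ",") + 1L),
      n_group2 = ifelse(.data$group2_active == "", 0L,
                        stringr::str_count(.data$group2_active, ",") + 1L),
      alternative = .data$n_group1 > 0L & .data$n_group2 > 0L)
}
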