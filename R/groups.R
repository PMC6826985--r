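#' Two-group sample annotation
#'
#' Builds the sample-group table used throughout the pipeline. Exactly two
#' distinct group labels are required and both must be non-empty. The method is
#' symmetric in its mathematics but asymmetric in naming: `group1` plays the
#' role the primary-cancer group plays in the study design (its activity excess
#' is tested by the "left" tail) and `group2` the metastatic group. The role
#' assignment is therefore explicit, never inferred from sort order.
#'
#' @param data A data frame with columns `sample_id` and `group`.
#' @param group1 Label to treat as group1. Defaults to the label of the first
#'   row, with a message, so scripted use should pass it explicitly.
#' @return A tibble of class `sample_groups` with columns `sample_id`, `group`
#'   and attributes `group1` / `group2`.
#' @examples
#' sg <- sample_groups(
#'   data.frame(sample_id = c("s1", "s2", "s3"),
#'              group = c("primary", "primary", "metastatic")),
#'   group1 = "primary")
#' group_labels(sg)
#' @export
sample_groups <- function(data, group1 = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("sample_id", "group") %in% names(data))) {
    abort("`data` must have columns `sample_id` and `group`")
  }
  data <- as_tibble(data[c("sample_id", "group")])
  data$sample_id <- as.character(data$sample_id)
  data$group <- as.character(data$group)
  if (anyDuplicated(data$sample_id)) {
    abort("duplicated sample ids in group table")
  }
  labs <- unique(data$group)
  if (length(labs) != 2L) {
    abort(sprintf("exactly two group labels required, found %d: %s",
                  length(labs), paste(labs, collapse = ", ")))
  }
  if (is.null(group1)) {
    group1 <- data$group[[1L]]
    inform(sprintf("using '%s' as group1 (first label in table)", group1))
  }
  if (!group1 %in% labs) {
    abort(sprintf("group1 label '%s' not present in group table", group1))
  }
  structure(data,
            group1 = group1,
            group2 = setdiff(labs, group1),
            class = c("sample_groups", class(data)))
}

#' @rdname sample_groups
#' @param x A `sample_groups` object.
#' @return `group_labels()` returns a named character vector
#'   `c(group1 = ..., group2 = ...)`.
#' @export
group_labels <- function(x) {
  stopifnot(inherits(x, "sample_groups"))
  c(group1 = attr(x, "group1"), group2 = attr(x, "group2"))
}

#' Sample ids belonging to one group role
#' @param x A `sample_groups` object.
#' @param role `"group1"` or `"group2"`.
#' @return Character vector of sample ids.
#' @export
group_members <- function(x, role = c("group1", "group2")) {
  role <- match.arg(role)
  x$sample_id[x$group == attr(x, role)]
}

#' Swap the two group roles
#'
#' Returns the same annotation with group1 and group2 exchanged. Useful for
#' symmetry checks: every test in the pipeline swaps its two tails under this
#' operation.
#' @param x A `sample_groups` object.
#' @return A `sample_groups` object with roles exchanged.
#' @export
swap_groups <- function(x) {
  stopifnot(inherits(x, "sample_groups"))
  attr(x, "group1") <- group_labels(x)[["group2"]]
  attr(x, "group2") <- setdiff(unique(x$group), attr(x, "group1"))
  x
}

# internal: check that every sample column of a wide table is labelled
check_samples_labelled <- function(sample_ids, groups) {
  missing <- setdiff(sample_ids, groups$sample_id)
  if (length(missing) > 0L) {
    abort(sprintf("samples without a group label: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  invisible(TRUE)
}
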