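#' Build a gene-set collection over a measured-gene universe
#'
#' A collection is a tibble with one row per set (`set_name`, `description`,
#' list-column `genes`) carrying the background universe as an attribute.
#' Members are intersected with the universe on construction; sets that become
#' empty are dropped with a warning. The universe is the enrichment background
#' N used by [classify_pathways()].
#'
#' @param sets Named list of character vectors (set name -> member genes).
#' @param universe Character vector of all measured gene symbols.
#' @param descriptions Optional named character vector of set descriptions.
#' @return A tibble of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (length(sets) == 0L) abort("empty gene-set list")
  if (is.null(names(sets)) || any(names(sets) == "")) abort("all sets must be named")
  if (anyDuplicated(names(sets))) {
    abort(sprintf("duplicate set name(s): %s",
                  paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", ")))
  }
  universe <- unique(as.character(universe))
  members <- lapply(sets, function(g) intersect(unique(as.character(g)), universe))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warn(sprintf("dropping %d set(s) empty after intersection with the universe", sum(empty)))
    members <- members[!empty]
  }
  if (length(members) == 0L) abort("no set survives intersection with the universe")
  desc <- rep("", length(members))
  if (!is.null(descriptions)) {
    hit <- match(names(members), names(descriptions))
    desc[!is.na(hit)] <- descriptions[hit[!is.na(hit)]]
  }
  out <- tibble(set_name = names(members),
                description = desc,
                genes = unname(members))
  structure(out, universe = universe,
            class = c("gene_set_collection", class(out)))
}

#' @rdname gene_set_collection
#' @param x A `gene_set_collection`.
#' @return `set_universe()` returns the background gene vector.
#' @export
set_universe <- function(x) {
  u <- attr(x, "universe")
  if (is.null(u)) abort("not a gene_set_collection: missing universe")
  u
}

# internal: named list view of the member column
set_list <- function(x) setNames(x$genes, x$set_name)
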