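#' Merge PMA tables from two platforms
#'
#' The two platforms measure disjoint sample sets (an error otherwise) and
#' possibly different probe sets. By default the probe union is kept and a
#' probe unmeasured on a platform is filled with Absent calls for that
#' platform's samples, so a gene measured on only one platform stays in the
#' analysis with its unmeasured samples inactive. With
#' `require_all_platforms = TRUE` (and a probe map) genes lacking probes on
#' either platform are dropped instead.
#'
#' @param a,b PMA tibbles (first column `probe_id`).
#' @param require_all_platforms Drop genes without probes on both platforms.
#' @param probe_map Probe-to-gene map, required when
#'   `require_all_platforms = TRUE`.
#' @return A merged PMA tibble covering all samples of both platforms.
#' @export
merge_pma_tables <- function(a, b, require_all_platforms = FALSE,
                             probe_map = NULL) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  sa <- names(a)[-1L]; sb <- names(b)[-1L]
  shared <- intersect(sa, sb)
  if (length(shared) > 0L) {
    abort(sprintf("platforms share sample id(s): %s",
                  paste(head(shared, 3L), collapse = ", ")))
  }
  probes <- union(a$probe_id, b$probe_id)
  fill_block <- function(tbl, samples) {
    m <- matrix("A", nrow = length(probes), ncol = length(samples),
                dimnames = list(probes, samples))
    hit <- match(tbl$probe_id, probes)
    for (s in samples) m[hit, s] <- tbl[[s]]
    m
  }
  merged <- dplyr::bind_cols(tibble(probe_id = probes),
                             as_tibble(fill_block(a, sa)),
                             as_tibble(fill_block(b, sb)))
  if (require_all_platforms) {
    if (is.null(probe_map)) {
      abort("require_all_platforms needs a probe_map")
    }
    gene_of <- setNames(probe_map$gene, probe_map$probe_id)
    genes_a <- unique(gene_of[intersect(a$probe_id, names(gene_of))])
    genes_b <- unique(gene_of[intersect(b$probe_id, names(gene_of))])
    keep_genes <- intersect(genes_a, genes_b)
    keep <- merged$probe_id %in% names(gene_of)[gene_of %in% keep_genes]
    n_drop <- length(setdiff(union(genes_a, genes_b), keep_genes))
    if (n_drop > 0L) {
      inform(sprintf("dropping %d gene(s) not measured on both platforms", n_drop))
    }
    merged <- merged[keep, , drop = FALSE]
  }
  merged
}
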