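#' One-tailed Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability for the first cell of the table
#' `[[a, b], [c, d]]` with all margins fixed. With X the first cell of a random
#' table drawn with the observed margins, `tail = "greater_first_cell"` returns
#' P(X >= a) and `tail = "less_first_cell"` returns P(X <= a). Degenerate
#' margins (an empty row or column) give p = 1. All arguments are vectorised.
#'
#' This is the workhorse behind both the per-gene activity test (is a gene
#' active in a larger fraction of group1 than group2 samples?) and the
#' per-pathway over-representation test.
#'
#' @param a,b,c,d Non-negative integer cell counts, first row `(a, b)`,
#'   second row `(c, d)`.
#' @param tail Which tail of the first-cell distribution to accumulate.
#' @return Numeric vector of exact p-values in `[0, 1]`.
#' @examples
#' fisher_one_tailed(8, 2, 2, 8, "greater_first_cell")  # ~0.0115
#' fisher_one_tailed(0, 10, 5, 5, "greater_first_cell") # 1
#' @export
fisher_one_tailed <- function(a, b, c, d,
                              tail = c("greater_first_cell", "less_first_cell")) {
  tail <- match.arg(tail)
  counts <- cbind(a, b, c, d)
  if (any(counts < 0)) abort("negative counts in 2x2 table")
  if (any(counts != floor(counts))) abort("non-integer counts in 2x2 table")
  # X ~ Hypergeometric(row1 total, row2 total, column1 total)
  m <- a + b
  n <- c + d
  k <- a + c
  if (tail == "greater_first_cell") {
    phyper(a - 1, m, n, k, lower.tail = FALSE)
  } else {
    phyper(a, m, n, k, lower.tail = TRUE)
  }
}

#' Hypergeometric overlap p-value between two gene sets
#'
#' Tests whether two pathways share more genes than expected by chance, given
#' the union universe of all pathway genes. With `nall` genes overall, `na` in
#' pathway A, `nb` in pathway B and `nab` shared, the standard variant returns
#' the upper tail P(X >= nab) of the hypergeometric distribution, i.e.
#' `1 - sum_{i=0}^{nab-1} C(na,i) C(nall-na, nb-i) / C(nall, nb)`.
#'
#' The `as_printed` variant starts the sum at i = 1 instead of i = 0; the two
#' differ by exactly the point mass P(X = 0). Both are provided because the
#' truncated sum appears in print in the literature while the named test is
#' the hypergeometric upper tail; `standard` is the default.
#'
#' @param na,nb Sizes of the two sets.
#' @param nab Size of their intersection.
#' @param nall Size of the union universe the sets are drawn from.
#' @param variant `"standard"` (upper hypergeometric tail) or `"as_printed"`.
#' @return A p-value (or vector of p-values; arguments are vectorised).
#' @examples
#' overlap_pvalue(10, 10, 5, 100)
#' overlap_pvalue(10, 10, 0, 100)  # 1
#' @export
overlap_pvalue <- function(na, nb, nab, nall,
                           variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  counts <- cbind(na, nb, nab, nall)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("overlap counts must be non-negative integers")
  }
  bad <- nab > pmin(na, nb) | na > nall | nb > nall | nb > nall - na + nab
  if (any(bad)) {
    abort("infeasible overlap counts: need nab <= min(na, nb) and nb <= nall - na + nab")
  }
  if (variant == "standard") {
    phyper(nab - 1, na, nall - na, nb, lower.tail = FALSE)
  } else {
    # literal truncated sum, lower index i = 1
    mapply(function(na, nb, nab, nall) {
      if (nab <= 1) return(1)
      i <- seq_len(nab - 1L)
      1 - sum(exp(lchoose(na, i) + lchoose(nall - na, nb - i) - lchoose(nall, nb)))
    }, na, nb, nab, nall)
  }
}

#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' Step-up adjusted p-values: with p-values sorted increasingly,
#' `q_(i) = min_{j >= i} min(1, p_(j) * n / j)`, mapped back to input order.
#' Written out explicitly so the adjustment used for the pathway-crosstalk
#' edges is self-contained; it agrees with `stats::p.adjust(method = "fdr")`,
#' which the test suite uses as an independent reference.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))  # all 0.05
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}
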