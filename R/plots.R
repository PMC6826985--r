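# ggplot2 views of the main result types.

#' @export
autoplot.gene_classification <- function(object, ...) {
  d <- tidy(object)
  d$log_p_left <- -log10(pmax(d$p_left, .Machine$double.xmin))
  d$log_p_right <- -log10(pmax(d$p_right, .Machine$double.xmin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_p_left, y = .data$log_p_right,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "-log10 p (group1 more active)",
                  y = "-log10 p (group2 more active)",
                  colour = "class",
                  title = "Per-gene differential activity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pathway_classification <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(d, c("p_g1", "p_g2"),
                           names_to = "direction", values_to = "p")
  d$direction <- ifelse(d$direction == "p_g1", "group1", "group2")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$pathway, -log10(.data$p)),
                                  y = -log10(pmax(.data$p, 1e-300)),
                                  fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 p",
                  title = "Pathway differential activation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pathway_network <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges
  if (nrow(nodes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty pathway network"))
  }
  # circular layout; no graph-drawing dependency needed at this scale
  theta <- seq(0, 2 * pi, length.out = nrow(nodes) + 1L)[seq_len(nrow(nodes))]
  lay <- tibble(pathway = nodes$pathway, x = cos(theta), y = sin(theta),
                class = nodes$class)
  if (nrow(edges) > 0L) {
    seg <- dplyr::left_join(edges, lay, by = c(pathway_a = "pathway")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(lay[c("pathway", "x", "y")],
                       by = c(pathway_b = "pathway"))
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   alpha = -log10(pmax(.data$q, 1e-300))),
      colour = "grey40")
  }
  p + ggplot2::geom_point(data = lay,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$class), size = 3) +
    ggplot2::geom_text(data = lay,
                       ggplot2::aes(x = .data$x * 1.08, y = .data$y * 1.08,
                                    label = .data$pathway), size = 2.5) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Pathway-crosstalk network", alpha = "-log10 q")
}

#' @export
autoplot.robustness_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(object$iterations,
                           c("gene_overlap_prop", "pathway_overlap_prop",
                             "cor_g1", "cor_g2"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Subsampling robustness across iterations") +
    ggplot2::theme_minimal()
}
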