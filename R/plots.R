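#' Plot a subgraph
#'
#' Deterministic circular layout (no graph-layout dependency): seeds and
#' added genes are interleaved around a circle in addition order, induced
#' edges drawn with width proportional to `|weight|`.
#'
#' @param object A `subgraph`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot subgraph
#' @export
autoplot.subgraph <- function(object, ...) {
  nd <- object$nodes
  n <- nrow(nd)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  nd$x <- cos(ang)
  nd$y <- sin(ang)
  ed <- object$edges
  ed <- left_join(ed, select(nd, "node", x1 = "x", y1 = "y"),
                  by = c(gene1 = "node"))
  ed <- left_join(ed, select(nd, "node", x2 = "x", y2 = "y"),
                  by = c(gene2 = "node"))
  ggplot() +
    geom_segment(data = ed,
                 aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                     yend = .data$y2, linewidth = abs(.data$weight)),
                 colour = "grey70", show.legend = FALSE) +
    geom_point(data = nd, aes(x = .data$x, y = .data$y, colour = .data$role),
               size = 3) +
    ggplot2::geom_text(data = nd,
                       aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                           label = .data$node), size = 2.8) +
    scale_colour_manual(values = c(seed = "#d95f02", added = "#1b9e77")) +
    ggplot2::coord_equal() + ggplot2::theme_void()
}

#' Plot the edge-weight distribution of a network
#'
#' @param object A `gene_network`.
#' @param ... Unused.
#' @return A ggplot histogram of edge weights.
#' @method autoplot gene_network
#' @export
autoplot.gene_network <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    labs(x = "edge weight (z scale)", y = "pairs",
         title = sprintf("%s network, %d edges", attr(object, "net_type"),
                         nrow(object))) +
    theme_minimal()
}

#' Plot a QC summary
#'
#' Per-sample means with +/- 1 sd bars, coloured by missing fraction.
#'
#' @param qc Output of [qc_summary()].
#' @return A ggplot.
#' @export
plot_qc <- function(qc) {
  d <- qc$samples
  ggplot(d, aes(x = .data$sample, y = .data$mean,
                colour = .data$missing_frac)) +
    geom_point() +
    geom_segment(aes(xend = .data$sample, y = .data$mean - .data$sd,
                     yend = .data$mean + .data$sd)) +
    labs(y = "sample mean +/- sd", colour = "missing") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Volcano plot of meta-analysis results
#'
#' @param meta Output of [meta_analyze()].
#' @param fdr q-value cutoff highlighted (default 0.05).
#' @return A ggplot.
#' @export
plot_meta_volcano <- function(meta, fdr = 0.05) {
  d <- mutate(meta, significant = .data$q <= fdr)
  ggplot(d, aes(x = .data$mu_hat, y = -log10(.data$p),
                colour = .data$significant)) +
    geom_point(alpha = 0.7) +
    scale_colour_manual(values = c(`TRUE` = "#d62728", `FALSE` = "grey60")) +
    labs(x = "pooled log2 fold change", y = "-log10 p") +
    theme_minimal()
}
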