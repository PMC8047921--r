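# ggplot2 visualizations of result objects.

#' Plot a Monte-Carlo presence screen
#'
#' Volcano-style view of the `Modulated` proteins: mean t statistic against
#' the upper bound of the p-value interval (on a -log10 scale), colored by
#' significance, with a marginal bar of the presence classes.
#'
#' @param object A `presence_mc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.presence_mc <- function(object, ...) {
  calls <- object$calls
  mod <- dplyr::filter(calls, .data$status == "Modulated")
  ggplot2::ggplot(mod, ggplot2::aes(x = .data$t_mean,
                                    y = -log10(pmax(.data$p_high, 1e-12)),
                                    color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = "dashed", color = "grey40") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "mean t statistic (A - B)",
      y = expression(-log[10] ~ "upper p bound"),
      color = "significant",
      title = paste0("Monte-Carlo screen: ", object$config$contrast[1], " vs ",
                     object$config$contrast[2]),
      subtitle = paste0(sum(calls$significant), " significant of ",
                        nrow(mod), " Modulated proteins")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a JTK-cycle screen
#'
#' Histogram of the exact p-values with the call threshold marked; a
#' well-behaved null screen is near-uniform, rhythmic signal piles up near 0.
#'
#' @param object A `jtk_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jtk_screen <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.02),
                            fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = object$config$p_threshold,
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "exact JTK p-value", y = "proteins",
                  title = "JTK-cycle screen",
                  subtitle = paste0(sum(object$results$passes), " proteins below p = ",
                                    object$config$p_threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a BGLS periodogram
#'
#' Normalized posterior over the period window with the best period marked.
#'
#' @param object A `bgls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bgls <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$period, y = .data$posterior)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = object$best_period, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "period (h)", y = "posterior probability",
                  title = "BGLS periodogram",
                  subtitle = paste0("best period ", round(object$best_period, 3), " h")) +
    ggplot2::theme_minimal()
}

#' Plot the three-detector Venn consensus as a region bar chart
#'
#' @param venn A [venn_counts()] tibble.
#' @return A ggplot object.
#' @export
plot_venn_regions <- function(venn) {
  venn$region <- factor(venn$region, levels = venn$region)
  ggplot2::ggplot(venn, ggplot2::aes(x = .data$region, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "proteins", title = "Detector overlap") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a projected PPI subnetwork
#'
#' Force-directed layout of the induced subnetwork, nodes colored by label.
#'
#' @param object A `ppi_projection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_projection <- function(object, ...) {
  g <- object$graph
  if (igraph::vcount(g) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "Empty projection") +
             ggplot2::theme_void())
  }
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  el <- igraph::as_edgelist(g)
  edges <- tibble(
    x = nodes$x[match(el[, 1], nodes$node)],
    y = nodes$y[match(el[, 1], nodes$node)],
    xend = nodes$x[match(el[, 2], nodes$node)],
    yend = nodes$y[match(el[, 2], nodes$node)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, color = .data$label),
                        size = 2.5) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
                       size = 2, vjust = -1) +
    ggplot2::labs(title = "Projected PPI subnetwork",
                  subtitle = paste0(object$summary$n_nodes, " nodes, ",
                                    object$summary$n_edges, " edges")) +
    ggplot2::theme_void()
}
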