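#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout; nodes coloured by module (unassigned
#' nodes hollow), positive edges solid blue, negative edges dashed red,
#' node size scaled logarithmically with mean abundance when available.
#'
#' @param object A `cooccur_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cooccur_network
#' @export
autoplot.cooccur_network <- function(object, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  pos <- setNames(seq_len(nrow(nodes)), nodes$otu_id)
  edges <- dplyr::mutate(object$edges,
                         x = nodes$x[pos[.data$otu_a]],
                         y = nodes$y[pos[.data$otu_a]],
                         xend = nodes$x[pos[.data$otu_b]],
                         yend = nodes$y[pos[.data$otu_b]])
  size <- if ("mean_abundance" %in% names(nodes)) {
    2 + log10(nodes$mean_abundance / min(nodes$mean_abundance) + 1)
  } else {
    3
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   colour = .data$sign, linetype = .data$sign),
      alpha = 0.6) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   fill = factor(.data$module)),
      shape = 21, size = size) +
    ggplot2::scale_colour_manual(values = c("+" = "steelblue",
                                            "-" = "firebrick"),
                                 name = "interaction") +
    ggplot2::scale_linetype_manual(values = c("+" = "solid",
                                              "-" = "dashed"),
                                   name = "interaction") +
    ggplot2::labs(fill = "module") +
    ggplot2::theme_void()
}

#' Cumulative significant interactions versus q-value threshold
#'
#' Number of positive and negative associations whose q-value is at or
#' below each threshold, up to `q_max`; the curve is non-decreasing by
#' construction and helps pick an edge-selection cutoff.
#'
#' @param results An `association_results` tibble.
#' @param q_max Largest threshold shown (default 0.05).
#' @return A ggplot object.
#' @export
plot_significance_curve <- function(results, q_max = 0.05) {
  res <- dplyr::filter(results, is.finite(.data$q), .data$q <= q_max)
  res <- dplyr::mutate(res, sign = ifelse(.data$z > 0,
                                          "positive", "negative"))
  res <- dplyr::arrange(res, .data$q)
  res <- dplyr::mutate(dplyr::group_by(res, .data$sign),
                       cumulative = dplyr::row_number())
  ggplot2::ggplot(res, ggplot2::aes(x = .data$q, y = .data$cumulative,
                                    linetype = .data$sign)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "q-value threshold",
                  y = "cumulative significant interactions",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' PCoA trajectories faceted by current regime and resource supply
#'
#' Samples of each microcosm are joined chronologically; facets split by
#' the selection regime active at sampling time (rows) and resource
#' supply (columns), so convergence of the community towards
#' regime-specific configurations is visible regardless of prehistory.
#'
#' @param ordination A `pcoa_ord`.
#' @param metadata Sample metadata with `current_regime`.
#' @return A ggplot object.
#' @export
plot_ordination_trajectories <- function(ordination, metadata) {
  coords <- dplyr::inner_join(ordination$coordinates, metadata,
                              by = "sample_id")
  coords <- dplyr::arrange(coords, .data$microcosm_id, .data$day)
  ggplot2::ggplot(coords,
                  ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                               group = .data$microcosm_id,
                               colour = .data$microcosm_id,
                               linetype = .data$resource_supply)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::geom_text(ggplot2::aes(label = .data$day), size = 2.5,
                       show.legend = FALSE) +
    ggplot2::facet_grid(current_regime ~ resource_supply) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", 100 * ordination$prop_explained[1]),
      y = sprintf("Axis 2 (%.1f%%)", 100 * ordination$prop_explained[2]),
      linetype = "supply") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
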