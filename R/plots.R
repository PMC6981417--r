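# ggplot2 views of spectra, abundance tables and differential pathway maps.

#' Plot an MS spectrum
#'
#' Stick plot of a peak list, optionally labelling annotated peaks with their
#' best candidate.
#'
#' @param spectrum An `ms_spectrum`.
#' @param annotation Optional `ganglio_annotation` for labels.
#' @param top_n Label at most this many most intense annotated peaks.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum, annotation = NULL, top_n = 10) {
  p <- ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, y = 0,
                                       yend = .data$intensity),
                          linewidth = 0.4) +
    ggplot2::labs(x = "m/z", y = "apex intensity",
                  title = attr(spectrum, "sample_id")) +
    ggplot2::theme_minimal()
  if (!is.null(annotation)) {
    lab <- best_candidates(annotation)
    lab <- utils::head(dplyr::arrange(lab, dplyr::desc(.data$intensity)), top_n)
    p <- p + ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = .data$peak_mz, y = .data$intensity, label = .data$species),
      vjust = -0.4, size = 2.8
    )
  }
  p
}

#' @export
autoplot.abundance_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample, y = .data$abundance_pct,
                               fill = .data$species)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "% of total ganglioside content", x = NULL,
                  fill = "species") +
    ggplot2::theme_minimal()
}

#' Render a differential pathway map
#'
#' Draws the pathway graph with node fill taken from the differential color
#' attributes set by [map_differential()] (grey = no data). Metabolites are
#' laid out by series and elongation step; gene nodes are listed beside the
#' map.
#'
#' @param graph A colored pathway graph.
#' @return A ggplot.
#' @export
plot_pathway <- function(graph) {
  nodes <- igraph::as_data_frame(graph, what = "vertices")
  edges <- igraph::as_data_frame(graph, what = "edges")
  lay <- igraph::layout_with_sugiyama(graph)$layout
  nodes$x <- lay[, 1]
  nodes$y <- lay[, 2]
  edges$x <- nodes$x[match(edges$from, nodes$name)]
  edges$y <- nodes$y[match(edges$from, nodes$name)]
  edges$xend <- nodes$x[match(edges$to, nodes$name)]
  edges$yend <- nodes$y[match(edges$to, nodes$name)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      color = "grey40"
    ) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name,
                   fill = I(.data$color)),
      size = 2.8
    ) +
    ggplot2::theme_void()
}
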