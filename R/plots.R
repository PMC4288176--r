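#' Plot a per-residue flexibility profile
#'
#' Line plot of normalized (or raw) per-residue values against the
#' sequential residue index -- the standard way of eyeballing which loop
#' residues are flexible.
#'
#' @param profile A `qg_profile` (normalised with [normalize_profile()]
#'   if the `normalized` column should be shown).
#' @param normalized Plot the `normalized` column if present (default
#'   `TRUE`).
#' @return A ggplot object.
#' @export
plot_flexibility <- function(profile, normalized = TRUE) {
  ycol <- if (normalized && "normalized" %in% names(profile))
    "normalized" else "value"
  df <- dplyr::mutate(profile,
                      index = if ("index" %in% names(profile))
                        .data$index else dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index,
                                   y = .data[[ycol]])) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_x_continuous(breaks = df$index,
                                labels = df$label) +
    ggplot2::labs(x = NULL,
                  y = if (ycol == "normalized") "normalized value"
                      else "value",
                  title = attr(profile, "source")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot orientation occupancy per base
#'
#' Stacked bar chart of the per-base orientation-category occupancy
#' table from [orientation_summary()].
#'
#' @param summary_tbl Output of [orientation_summary()].
#' @return A ggplot object.
#' @export
plot_orientation_summary <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data$label, y = .data$occupancy,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "occupancy (%)", fill = "orientation") +
    ggplot2::theme_minimal()
}

#' Plot a cluster transition graph
#'
#' Circular node layout with node area proportional to cluster
#' population and edges labelled by transition counts -- the
#' conformational-exchange diagram for a clustered ensemble.
#'
#' @param model A `qg_clusters`.
#' @param graph The matching `qg_transitions` (default: computed from
#'   `model`).
#' @return A ggplot object.
#' @export
plot_transition_graph <- function(model, graph = transition_graph(model)) {
  k <- model$k
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  nodes <- tibble::tibble(cluster = seq_len(k),
                          x = cos(th), y = sin(th),
                          population = model$populations)
  ue <- undirected_edges(graph)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(ue)) {
    seg <- dplyr::mutate(ue,
                         x = nodes$x[.data$a], y = nodes$y[.data$a],
                         xend = nodes$x[.data$b], yend = nodes$y[.data$b])
    p <- p +
      ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, linewidth = .data$count),
        color = "grey55") +
      ggplot2::geom_text(
        data = dplyr::mutate(seg, mx = (.data$x + .data$xend) / 2,
                             my = (.data$y + .data$yend) / 2),
        ggplot2::aes(x = .data$mx, y = .data$my,
                     label = .data$count),
        size = 3, color = "grey25")
  }
  p +
    ggplot2::geom_point(ggplot2::aes(size = .data$population),
                        color = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$cluster),
                       color = "white", size = 3) +
    ggplot2::scale_size_area(max_size = 18) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(size = "population", linewidth = "transitions")
}

#' Autoplot methods
#'
#' `autoplot()` dispatches `qg_profile` to [plot_flexibility()] and
#' `qg_clusters` to [plot_transition_graph()].
#'
#' @param object A `qg_profile` or `qg_clusters`.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @name autoplot-quadgeom
NULL

#' @rdname autoplot-quadgeom
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.qg_profile <- function(object, ...) plot_flexibility(object, ...)

#' @rdname autoplot-quadgeom
#' @exportS3Method ggplot2::autoplot
autoplot.qg_clusters <- function(object, ...) {
  plot_transition_graph(object, ...)
}
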