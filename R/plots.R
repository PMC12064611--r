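#' Plot a 2-D embedding
#'
#' Scatter plot of the embedding; with an assignment, points are colored by
#' cluster name (unassigned points in grey).
#'
#' @param object An `embedding2d`.
#' @param assignment Optional `cluster_assignment` over the same points.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.embedding2d <- function(object, assignment = NULL, ...) {
  df <- as_tibble(object)
  p <- attr(object, "params")
  if (!is.null(assignment)) {
    tb <- cluster_table(assignment)
    df$code <- tb$name[match(assignment$cluster_id, tb$cluster_id)]
    df$code[is.na(df$code)] <- "(unassigned)"
    gg <- ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v, colour = .data$code)) +
      ggplot2::geom_point(size = 0.8, alpha = 0.8) +
      ggplot2::scale_colour_brewer(palette = "Set1", na.value = "grey70")
  } else {
    gg <- ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v)) +
      ggplot2::geom_point(size = 0.8, alpha = 0.8, colour = "steelblue")
  }
  gg +
    ggplot2::labs(
      x = "UMAP 1", y = "UMAP 2",
      title = sprintf("2-D embedding (n_neighbors = %d, min_dist = %g)",
                      p$n_neighbors, p$min_dist)) +
    ggplot2::theme_minimal()
}

#' Plot a behavior timeline
#'
#' The coded time series: one horizontal band per behavior code, a filled
#' tile wherever that code is active.
#'
#' @param object A `behavior_timeline`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.behavior_timeline <- function(object, ...) {
  df <- as_tibble(object)
  df$t_s <- df$time_ms / 1000
  ggplot2::ggplot(df[df$code != "NONE", , drop = FALSE],
                  ggplot2::aes(x = .data$t_s, y = .data$code,
                               fill = .data$code)) +
    ggplot2::geom_tile(height = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Behavior coding") +
    ggplot2::theme_minimal()
}

#' Plot a dwell-density map
#'
#' @param object A `kde_dwell` from [kde_dwell()].
#' @param ... Ignored.
#' @return A ggplot (y axis reversed to match image coordinates).
#' @export
autoplot.kde_dwell <- function(object, ...) {
  df <- expand.grid(x = object$x, y = object$y)
  df$density <- as.vector(object$z)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("Dwell density, keypoint %d", object$keypoint)) +
    ggplot2::theme_minimal()
}

#' Plot feature series
#'
#' Line plot of every feature column over time, faceted by feature.
#'
#' @param object A `feature_series`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.feature_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), cols = feature_columns(object),
                              names_to = "feature", values_to = "value")
  long$t_s <- long$time_ms / 1000
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::facet_wrap(~feature, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.embedding2d <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.behavior_timeline <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.kde_dwell <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.feature_series <- function(x, ...) print(autoplot(x, ...))
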