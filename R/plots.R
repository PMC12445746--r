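# ggplot2 visualisations: environments, views, RFFs, routes.

#' Plot an environment's landmarks
#'
#' Canopy and trunk footprints as filled circles (approximated by sized
#' points), coloured by tree height.
#'
#' @param object an `ant_environment`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ant_environment <- function(object, ...) {
  lm <- object$landmarks
  ggplot2::ggplot(lm, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$canopy_radius,
                                     colour = .data$height), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", size = "canopy radius (m)",
                  colour = "height (m)") +
    ggplot2::theme_minimal()
}

#' Plot a panoramic view
#'
#' @param object a `pano_view`.
#' @param ... unused.
#' @return a ggplot raster of the view (dark = landmark, light = sky).
#' @export
autoplot.pano_view <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$intensity <- as.vector(t(m))[(df$row - 1) * ncol(m) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "grey20", high = "grey95",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (2 deg each)", y = "row", fill = "intensity") +
    ggplot2::theme_void()
}

#' Plot a rotational familiarity function
#'
#' @param object an `ant_rff`.
#' @param ... unused.
#' @return a ggplot of novelty versus relative heading.
#' @export
autoplot.ant_rff <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$psi, .data$novelty)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = vbo_heading(object), linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "relative heading psi (deg)",
                  y = "normalised novelty") +
    ggplot2::theme_minimal()
}

#' Plot training and test routes over the environment
#'
#' @param training an `ant_training`.
#' @param recaps a single `ant_recap` or a list of them.
#' @param env optionally, the environment to draw landmarks from.
#' @return a ggplot: training route (orange), test routes (grey), goal (x).
#' @export
plot_routes <- function(training, recaps = list(), env = NULL) {
  if (inherits(recaps, "ant_recap")) recaps <- list(recaps)
  p <- ggplot2::ggplot()
  if (!is.null(env)) {
    p <- p + ggplot2::geom_point(
      data = env$landmarks,
      ggplot2::aes(.data$x, .data$y, size = .data$canopy_radius),
      colour = "darkgreen", alpha = 0.35, show.legend = FALSE
    ) + ggplot2::scale_size_area(max_size = 4)
  }
  for (r in recaps) {
    p <- p + ggplot2::geom_path(data = r$route$poses,
                                ggplot2::aes(.data$x, .data$y),
                                colour = "grey40", linewidth = 0.3)
  }
  p +
    ggplot2::geom_path(data = training$route$poses,
                       ggplot2::aes(.data$x, .data$y),
                       colour = "orange", linewidth = 0.8) +
    ggplot2::annotate("point", x = training$goal[1], y = training$goal[2],
                      shape = 4, size = 3, colour = "orange") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
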