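# ggplot2 displays for the main result types.

#' Plot Kaplan-Meier curves
#'
#' Step curves per stratum from a [km_logrank()] fit, annotated with the
#' log-rank p-value.
#'
#' @param x a `km_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
plot_km <- function(x, ...) {
  curves <- dplyr::group_by(x$curves, .data$stratum)
  start <- dplyr::summarise(curves, time = 0, surv = 1)
  dat <- dplyr::bind_rows(start, x$curves[c("stratum", "time", "surv")])
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$surv, colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability",
                  subtitle = sprintf("log-rank p = %.3g", x$p)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.km_result <- function(object, ...) plot_km(object, ...)

#' Plot a marker point pattern over its annotation
#'
#' Shows the cell positions, the TC polygon and the IM band limits.
#'
#' @param points data frame with `x`, `y` in micrometres.
#' @param annotation a [tumor_annotation()].
#' @param sample_max at most this many points are drawn.
#' @return A ggplot.
#' @export
plot_pattern <- function(points, annotation, sample_max = 20000) {
  if (nrow(points) > sample_max)
    points <- points[sample.int(nrow(points), sample_max), ]
  poly <- tibble::tibble(x = annotation$tc_polygon[, 1],
                         y = annotation$tc_polygon[, 2])
  lab <- assign_region(points, annotation)
  ggplot2::ggplot(lab, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$region), size = 0.3, alpha = 0.6) +
    ggplot2::geom_polygon(data = poly, fill = NA, colour = "black", linewidth = 0.4) +
    ggplot2::coord_equal(xlim = annotation$extent[1:2], ylim = annotation$extent[3:4]) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot per-tile densities as a heat map
#'
#' @param tiles a [tile_densities()] tibble.
#' @return A ggplot.
#' @export
plot_tile_density <- function(tiles) {
  ggplot2::ggplot(tiles, ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                      ymin = .data$ymin, ymax = .data$ymax,
                                      fill = .data$density)) +
    ggplot2::geom_rect() +
    ggplot2::scale_fill_viridis_c(name = "cells/mm²") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
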