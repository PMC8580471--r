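#' Plot methods for simulation results
#'
#' `autoplot()` methods: energy traces for an aggregation log (the time
#' history of the five components and the total), stress-strain and energy
#' curves for a stretch record, band-normalised orientation probabilities,
#' and a grey-scale rendering of a projection image.
#'
#' @param object a `bd_log`, `stretch_record`, `orientation_stats` result
#'   of [orientation_probability()], or `projection_image`.
#' @param ... unused.
#' @return A ggplot object.
#' @name autoplot-fibrinbd
NULL

energy_long <- function(d) {
  tidyr::pivot_longer(
    dplyr::select(d, dplyr::any_of(c("time", "eps")),
                  dplyr::all_of(c("W_S", "W_B", "W_T", "W_A", "W_R",
                                  "W_total"))),
    cols = dplyr::starts_with("W"),
    names_to = "component", values_to = "energy")
}

#' @rdname autoplot-fibrinbd
#' @export
autoplot.bd_log <- function(object, ...) {
  d <- energy_long(tibble::as_tibble(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time * 1e3, y = .data$energy,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ms)", y = "energy (J)", colour = NULL)
}

#' @rdname autoplot-fibrinbd
#' @export
autoplot.stretch_record <- function(object, ...) {
  d <- tibble::as_tibble(object)
  if ("stress" %in% names(d)) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$eps, y = .data$stress)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = expression(epsilon[z]),
                    y = expression(sigma[z] ~ "(Pa)"))
  } else {
    ggplot2::ggplot(energy_long(d),
                    ggplot2::aes(x = .data$eps, y = .data$energy,
                                 colour = .data$component)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = expression(epsilon[z]), y = "energy (J)",
                    colour = NULL)
  }
}

#' @rdname autoplot-fibrinbd
#' @export
autoplot.projection_image <- function(object, ...) {
  px <- attr(object, "pixel")
  d <- expand.grid(x = seq_len(nrow(object)), y = seq_len(ncol(object)))
  d$lum <- as.vector(unclass(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x * px * 1e6,
                                  y = .data$y * px * 1e6,
                                  fill = .data$lum)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Plot an orientation probability table
#'
#' @param prob output of [orientation_probability()].
#' @return A ggplot object.
#' @export
plot_orientation <- function(prob) {
  ggplot2::ggplot(prob,
                  ggplot2::aes(x = (.data$lower + .data$upper) / 2 * 180 / pi,
                               y = .data$density)) +
    ggplot2::geom_col(width = 12) +
    ggplot2::labs(x = expression("<" * theta * "> (deg)"),
                  y = "probability / band area")
}
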