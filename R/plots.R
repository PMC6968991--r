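#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the field profiles of a simulation
#'
#' One panel per snapshot time, one line per field.
#'
#' @param object An `invasion_sim` object.
#' @param fields Fields to draw (default all five).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.invasion_sim <- function(object,
                                  fields = c("S", "T_A", "T_M", "L", "M"),
                                  ...) {
  d <- tidy(object)
  d <- d[d$field %in% fields, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$value,
                                  colour = .data$field)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position (dimensionless)", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a competition sweep
#'
#' @param object An `invasion_sweep` tibble from [run_competition_sweep()].
#' @param metric Column to fill by: `"front_either"` (default) or `"mass"`.
#' @param mask_disregarded Blank out combinations where both populations
#'   were flagged as too small (default `TRUE` for `"mass"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.invasion_sweep <- function(object, metric = c("front_either",
                                                       "mass"),
                                    mask_disregarded = NULL, ...) {
  metric <- match.arg(metric)
  if (is.null(mask_disregarded)) mask_disregarded <- metric == "mass"
  d <- tibble::as_tibble(as.data.frame(object))
  if (mask_disregarded) {
    d[[metric]][d$disregard_TA & d$disregard_TM] <- NA_real_
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$c_MA, y = .data$c_AM,
                                  fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "white") +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(c["M,A"]), y = expression(c["A,M"])) +
    ggplot2::theme_minimal()
}

#' Front position over time for a single-population run
#'
#' @param object A `single_population_run` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.single_population_run <- function(object, ...) {
  ggplot2::ggplot(object$front_series,
                  ggplot2::aes(x = .data$time, y = .data$front)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (dimensionless, log scale)",
                  y = "front position",
                  title = paste(object$which, "only")) +
    ggplot2::theme_minimal()
}

#' Regime map of the competition plane
#'
#' Tile plot of the four invasion scenarios predicted by the linear
#' stability analysis on a regular grid of the two competition
#' coefficients.
#'
#' @param c_values Values per axis (default 41 points on `[0, 2]`).
#' @param tol Boundary tolerance passed to [classify_regime()].
#' @return A ggplot object.
#' @export
plot_regime_map <- function(c_values = seq(0, 2, length.out = 41),
                            tol = 1e-6) {
  d <- tidyr::expand_grid(c_MA = c_values, c_AM = c_values)
  d$regime <- classify_regime(d$c_MA, d$c_AM, tol = tol)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$c_MA, y = .data$c_AM,
                                  fill = .data$regime)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(c["M,A"]), y = expression(c["A,M"]),
                  fill = "regime") +
    ggplot2::theme_minimal()
}
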