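#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation into long format
#'
#' @param x An `invasion_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `time`, `x`, `field`, `value`.
#' @export
tidy.invasion_sim <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(as.data.frame(x)),
                      cols = c("S", "T_A", "T_M", "L", "M"),
                      names_to = "field", values_to = "value") |>
    dplyr::mutate(field = factor(.data$field,
                                 levels = c("S", "T_A", "T_M", "L", "M")))
}

#' One-row summary of a simulation
#'
#' @param x An `invasion_sim` object.
#' @param eps Front threshold passed to [front_position()].
#' @param ... Unused.
#' @return A tibble with the grid size, final time, final front positions,
#'   final tumour mass and the most negative value attained (a check on the
#'   negativity stabilisation).
#' @export
glance.invasion_sim <- function(x, eps = 1e-2, ...) {
  t_max <- max(x$time)
  fin <- snapshot_at(x, t_max)
  g <- attr(x, "grid")
  tibble::tibble(
    n_points = g$n_points,
    n_snapshots = length(unique(x$time)),
    t_max = t_max,
    front_T_A = front_position(fin, "T_A", eps = eps),
    front_T_M = front_position(fin, "T_M", eps = eps),
    front_either = front_position(fin, "either", eps = eps),
    mass = tumour_mass(fin),
    min_value = min(as.matrix(fin[, c("S", "T_A", "T_M", "L", "M")]))
  )
}

#' Tidy a single-population run
#'
#' @param x A `single_population_run` object.
#' @param ... Unused.
#' @return The front-position time series as a tibble.
#' @export
tidy.single_population_run <- function(x, ...) x$front_series

#' @param x A `single_population_run` object.
#' @param ... Unused.
#' @rdname tidy.single_population_run
#' @export
glance.single_population_run <- function(x, ...) {
  tibble::tibble(which = x$which,
                 stall_position = x$stall_position,
                 stalled = x$stalled,
                 t_end = max(x$front_series$time))
}

#' Tidy a perturbation experiment
#'
#' @param x A `perturbation_experiment` object.
#' @param ... Unused.
#' @return The one-row summary tibble.
#' @export
tidy.perturbation_experiment <- function(x, ...) x$summary

#' Tidy a kappa-sensitivity study
#'
#' @param x A `kappa_sensitivity` object.
#' @param ... Unused.
#' @return The per-kappa asymmetry tibble.
#' @export
tidy.kappa_sensitivity <- function(x, ...) x$asymmetry
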