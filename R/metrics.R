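#' Position of the invading tumour front
#'
#' Two constructions are offered. The default `threshold` front is the
#' largest `x` at which the species density still reaches `eps`, linearly
#' interpolated between grid points; it is robust and monotone in `eps`.
#' The `max_rate` front is the location of the most negative instantaneous
#' time derivative of the species field (computed through [assemble_rhs()]),
#' offered as an alternative reading of derivative-based front definitions;
#' both are reported by the sweep driver.
#'
#' @param state A data frame with columns `x, S, T_A, T_M, L, M`.
#' @param species `"either"` (the default; the maximum of the two phenotype
#'   fronts), `"T_A"` or `"T_M"`.
#' @param method `"threshold"` (default) or `"max_rate"`.
#' @param eps Detection threshold for the threshold method (default 1e-2).
#' @param params,grid Required for `method = "max_rate"` (the time
#'   derivative must be assembled).
#' @return The front position, or `NA_real_` if the species is everywhere
#'   below `eps` (an absent population, deliberately distinct from a front
#'   at 0).
#' @export
front_position <- function(state, species = c("either", "T_A", "T_M"),
                           method = c("threshold", "max_rate"), eps = 1e-2,
                           params = NULL, grid = NULL) {
  species <- match.arg(species)
  method <- match.arg(method)
  state <- as.data.frame(state)
  stopifnot("x" %in% names(state))
  if (species == "either") {
    fa <- front_position(state, "T_A", method, eps, params, grid)
    fm <- front_position(state, "T_M", method, eps, params, grid)
    if (is.na(fa) && is.na(fm)) return(NA_real_)
    return(max(fa, fm, na.rm = TRUE))
  }
  v <- state[[species]]
  x <- state$x
  if (method == "max_rate") {
    if (is.null(params) || is.null(grid)) {
      stop("method = 'max_rate' needs params and grid to assemble d/dt")
    }
    if (all(v < eps)) return(NA_real_)
    d <- assemble_rhs(state, params, grid)
    dv <- d[[paste0("d", species)]]
    return(x[which.min(dv)])
  }
  idx <- which(v >= eps)
  if (!length(idx)) return(NA_real_)
  i <- max(idx)
  if (i == length(v)) return(x[i])
  # linear interpolation of the downward eps-crossing between i and i+1
  x[i] + (v[i] - eps) / (v[i] - v[i + 1]) * (x[i + 1] - x[i])
}

#' Total tumour mass
#'
#' Trapezoidal quadrature of `T_A + T_M` over the domain; exact for constant
#' and piecewise-linear fields.
#'
#' @param state A data frame with columns `x, T_A, T_M`.
#' @return The integrated mass (non-negative for non-negative fields).
#' @export
tumour_mass <- function(state) {
  state <- as.data.frame(state)
  pracma::trapz(state$x, state$T_A + state$T_M)
}

#' Integrated size of one population
#'
#' @param state A data frame with columns `x` and the species column.
#' @param species `"T_A"` or `"T_M"`.
#' @return Trapezoidal integral of the species over the domain.
#' @export
population_size <- function(state, species = c("T_A", "T_M")) {
  species <- match.arg(species)
  state <- as.data.frame(state)
  pracma::trapz(state$x, state[[species]])
}

#' Should a small population be disregarded?
#'
#' Summary measures computed from very sparse populations are numerically
#' fragile; sweep analyses drop species whose integral falls strictly below
#' the cut-off 0.1 (the boundary value itself is kept).
#'
#' @param state A data frame with columns `x` and the species column.
#' @param species `"T_A"` or `"T_M"`.
#' @param cutoff Disregard threshold (default 0.1, strict).
#' @return `TRUE` if the population is to be disregarded.
#' @export
small_population_flag <- function(state, species = c("T_A", "T_M"),
                                  cutoff = 0.1) {
  population_size(state, species) < cutoff
}

#' Mean front speed over a time window
#'
#' @param sim An `invasion_sim` object.
#' @param species Passed to [front_position()].
#' @param window Two snapshot times `c(t1, t2)` stored in `sim`.
#' @param eps Front threshold.
#' @return `(front(t2) - front(t1)) / (t2 - t1)` in dimensionless units, or
#'   `NA_real_` if the population is absent at either endpoint.
#' @export
invasion_speed <- function(sim, species = "either", window = c(25, 50),
                           eps = 1e-2) {
  stopifnot(length(window) == 2, window[2] > window[1])
  f1 <- front_position(snapshot_at(sim, window[1]), species, eps = eps)
  f2 <- front_position(snapshot_at(sim, window[2]), species, eps = eps)
  if (is.na(f1) || is.na(f2)) return(NA_real_)
  (f2 - f1) / (window[2] - window[1])
}

#' Dimensional unit scales
#'
#' The rescaling underlying the dimensionless model corresponds to a time
#' scale of 11.57 days per dimensionless time unit and a spatial scale of
#' 2.24 cm per dimensionless length unit.
#'
#' @param days_per_time Days per dimensionless time unit (default 11.57).
#' @param cm_per_length Centimetres per dimensionless length unit
#'   (default 2.24).
#' @return An object of class `unit_scales`.
#' @export
unit_scales <- function(days_per_time = 11.57, cm_per_length = 2.24) {
  if (days_per_time <= 0 || cm_per_length <= 0) {
    stop("unit scales must be positive")
  }
  structure(list(days_per_time = days_per_time,
                 cm_per_length = cm_per_length), class = "unit_scales")
}

#' Convert a dimensionless quantity to dimensional units
#'
#' @param value Dimensionless value(s).
#' @param kind `"time"` (to days), `"length"` (to cm), `"speed"` (to
#'   cm/day) or `"speed_per_year"` (to cm/year).
#' @param scales A [unit_scales()] object.
#' @return The converted value(s).
#' @examples
#' to_dimensional(50, "time")    # ~578.5 days
#' to_dimensional(1, "length")   # 2.24 cm
#' @export
to_dimensional <- function(value, kind = c("time", "length", "speed",
                                           "speed_per_year"),
                           scales = unit_scales()) {
  kind <- match.arg(kind)
  stopifnot(inherits(scales, "unit_scales"))
  switch(kind,
         time = value * scales$days_per_time,
         length = value * scales$cm_per_length,
         speed = value * scales$cm_per_length / scales$days_per_time,
         speed_per_year = value * scales$cm_per_length /
           scales$days_per_time * 365)
}
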