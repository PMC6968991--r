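#' Equi-spaced one-dimensional grid
#'
#' @param n_points Number of grid points (default 200).
#' @param length Domain length in dimensionless units (default 1).
#' @return An object of class `grid_1d` with elements `n_points`, `length`,
#'   `h` (spacing) and `x` (coordinates).
#' @export
grid_1d <- function(n_points = 200, length = 1) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 3) {
    stop("n_points must be a single number >= 3")
  }
  if (!is.numeric(length) || length <= 0) stop("domain length must be positive")
  n_points <- as.integer(n_points)
  structure(list(n_points = n_points, length = length,
                 h = length / (n_points - 1),
                 x = seq(0, length, length.out = n_points)),
            class = "grid_1d")
}

#' @export
print.grid_1d <- function(x, ...) {
  cat(sprintf("<grid_1d> %d points on [0, %g], h = %g\n",
              x$n_points, x$length, x$h))
  invisible(x)
}

#' Regularised step function
#'
#' A smooth, compactly supported transition from 1 to 0 used to build
#' initial tumour/tissue interfaces:
#' \deqn{f(x;\sigma,\omega)= 1 \ \mathrm{for}\ x<\sigma-\omega,\quad
#'   \exp\!\left(1-\frac{1}{1-((x-\sigma+\omega)/\omega)^2}\right)
#'   \ \mathrm{for}\ \sigma-\omega \le x < \sigma,\quad 0\ \mathrm{otherwise}.}
#' The function is continuous in `x` and non-increasing; at `x = sigma-omega`
#' the middle branch evaluates to `exp(0) = 1`, matching the left branch.
#'
#' @param x Positions (vectorised).
#' @param sigma Location of the (right end of the) transition.
#' @param omega Sharpness: the transition occupies `[sigma-omega, sigma)`.
#' @return Values in `[0, 1]`.
#' @examples
#' regularised_step(c(0.05, 0.15, 0.25), sigma = 0.2, omega = 0.1)
#' @export
regularised_step <- function(x, sigma, omega) {
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0) {
    stop("omega must be a single positive number")
  }
  z <- (x - sigma + omega) / omega
  out <- numeric(length(x))
  out[x < sigma - omega] <- 1
  mid <- x >= sigma - omega & x < sigma
  out[mid] <- exp(1 - 1 / (1 - z[mid]^2))
  out
}

#' Initial-condition specification
#'
#' Shape parameters of the initial data. Each profile is a regularised step
#' whose full-density plateau extends to `sigma` and whose smooth transition
#' occupies `[sigma, sigma + omega]`: the tumour fields (and acid) start at
#' density 1 on `[0, sigma_tumour]`, while stroma and matrix are absent
#' there and rise to 1 beyond `sigma_tissue + omega`. Presence flags allow
#' single-population experiments (the step function itself has no way to
#' express an absent population).
#'
#' @param sigma_tissue Infiltration depth for stroma and matrix
#'   (default 0.2): `S` and `M` vanish on `[0, sigma_tissue]`.
#' @param sigma_tumour Initial tumour extent (default 0.1): `T_A`, `T_M` and
#'   `L` are at density 1 on `[0, sigma_tumour]`.
#' @param omega Boundary sharpness (default 0.1).
#' @param include_TA,include_TM Presence flags for the two phenotypes.
#' @return An object of class `initial_condition_spec`.
#' @export
initial_condition_spec <- function(sigma_tissue = 0.2, sigma_tumour = 0.1,
                                   omega = 0.1, include_TA = TRUE,
                                   include_TM = TRUE) {
  if (!is.numeric(omega) || omega <= 0) stop("omega must be positive")
  for (s in c(sigma_tissue, sigma_tumour)) {
    if (!is.numeric(s) || s <= 0) stop("sigma values must be positive")
    if (omega > s) stop("omega must not exceed sigma")
  }
  structure(list(sigma_tissue = sigma_tissue, sigma_tumour = sigma_tumour,
                 omega = omega, include_TA = isTRUE(include_TA),
                 include_TM = isTRUE(include_TM)),
            class = "initial_condition_spec")
}

#' Build the initial state on a grid
#'
#' Assembles the five fields from regularised steps:
#' `S = M = 1 - f`, placed by `sigma_tissue`, and `T_A = T_M = L = f`,
#' placed by `sigma_tumour` (tumour fields additionally gated by their
#' presence flags; the acid profile is always seeded with the tumour).
#'
#' @param grid A [grid_1d()] object.
#' @param ics An [initial_condition_spec()].
#' @return A tibble with columns `x, S, T_A, T_M, L, M`.
#' @examples
#' g <- grid_1d(50)
#' head(initial_state(g))
#' @export
initial_state <- function(grid = grid_1d(), ics = initial_condition_spec()) {
  stopifnot(inherits(grid, "grid_1d"), inherits(ics, "initial_condition_spec"))
  if (ics$sigma_tissue >= grid$length || ics$sigma_tumour >= grid$length) {
    stop("sigma must be smaller than the domain length")
  }
  if (ics$sigma_tissue + ics$omega > grid$length) {
    stop("tissue transition zone extends beyond the domain")
  }
  x <- grid$x
  tissue_step <- regularised_step(x, ics$sigma_tissue + ics$omega, ics$omega)
  tumour_step <- regularised_step(x, ics$sigma_tumour + ics$omega, ics$omega)
  tibble::tibble(
    x = x,
    S = 1 - tissue_step,
    T_A = if (ics$include_TA) tumour_step else rep(0, length(x)),
    T_M = if (ics$include_TM) tumour_step else rep(0, length(x)),
    L = tumour_step,
    M = 1 - tissue_step
  )
}
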