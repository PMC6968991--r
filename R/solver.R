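#' Solver settings
#'
#' @param rel_tol,abs_tol Relative and absolute integration tolerances
#'   (default `1e-10` each).
#' @param stabilisation_rate Rate `lambda` of the linear restoring term
#'   `-lambda * u` applied wherever a field value `u` has gone negative
#'   (default 100). Set to 0 to disable the guard.
#' @param extinction_threshold Density floor below which the local logistic
#'   source of a cell field (`S`, `T_A`, `T_M`) is switched off
#'   (default 1e-6). A stiff implicit integrator tolerates state noise at
#'   the absolute-tolerance level; without a floor, such noise seeds
#'   vanishingly small populations in regions the cells cannot physically
#'   reach (most visibly beyond an intact-matrix wall, where the tumour
#'   mobility is exactly zero) and the seeds then grow exponentially
#'   wherever acid has cleared the stroma. The floor must exceed `abs_tol`
#'   and lies far below the front-detection threshold (1e-2).
#' @param use_compiled Use the compiled right-hand side (default `TRUE`);
#'   `FALSE` falls back to the pure-R [assemble_rhs()], which is much slower
#'   but convenient for instrumentation.
#' @param max_steps Maximum internal integrator steps per output interval.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-10, abs_tol = 1e-10,
                            stabilisation_rate = 100,
                            extinction_threshold = 1e-6,
                            use_compiled = TRUE, max_steps = 500000L) {
  if (rel_tol <= 0 || abs_tol <= 0) stop("tolerances must be positive")
  if (stabilisation_rate < 0) stop("stabilisation_rate must be >= 0")
  if (extinction_threshold < 0) stop("extinction_threshold must be >= 0")
  if (extinction_threshold > 0 && extinction_threshold <= abs_tol) {
    warning("extinction_threshold should exceed abs_tol to be effective")
  }
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 stabilisation_rate = stabilisation_rate,
                 extinction_threshold = extinction_threshold,
                 use_compiled = isTRUE(use_compiled),
                 max_steps = as.integer(max_steps)),
            class = "solver_settings")
}

#' Variable-diffusion central second difference
#'
#' The flux-divergence approximation
#' \deqn{\partial_x (D \partial_x u)|_r \approx \frac{1}{2h^2}\left[
#'   (D_{r-1}+D_r)u_{r-1} - (D_{r-1}+2D_r+D_{r+1})u_r +
#'   (D_r+D_{r+1})u_{r+1}\right].}
#' With constant `D` this reduces to `D` times the standard three-point
#' Laplacian. When `r` is `NULL` the operator is applied at every grid point,
#' using ghost-point reflection of both `u` and `D` (`u_0 = u_2`,
#' `D_0 = D_2`, and symmetrically on the right) to enforce zero flux; the
#' reflected ghosts make the discrete operator conservative under
#' trapezoidal summation.
#'
#' @param u Field values on the grid.
#' @param D Mobility values on the grid (same length as `u`).
#' @param h Grid spacing.
#' @param r Optional single interior index (in `2:(length(u)-1)`); if given,
#'   only that point's value is returned and no ghost points are involved.
#' @return Numeric vector (or scalar for pointwise use).
#' @export
diffusion_stencil <- function(u, D, h, r = NULL) {
  n <- length(u)
  stopifnot(length(D) == n, h > 0)
  if (!is.null(r)) {
    if (r < 2 || r > n - 1) {
      stop("r must be an interior index in 2:(n-1)")
    }
    return(((D[r - 1] + D[r]) * u[r - 1] -
              (D[r - 1] + 2 * D[r] + D[r + 1]) * u[r] +
              (D[r] + D[r + 1]) * u[r + 1]) / (2 * h^2))
  }
  ue <- c(u[2], u, u[n - 1])
  De <- c(D[2], D, D[n - 1])
  il <- 1:n; ic <- 2:(n + 1); ir <- 3:(n + 2)
  ((De[il] + De[ic]) * ue[il] -
     (De[il] + 2 * De[ic] + De[ir]) * ue[ic] +
     (De[ic] + De[ir]) * ue[ir]) / (2 * h^2)
}

#' Negativity-stabilisation term
#'
#' Integration of the stiff system can transiently push field values a tiny
#' amount below zero. A linear restoring contribution `-lambda * u` is added
#' at every point where a field is negative (and 0 elsewhere), steering the
#' solution back without introducing the non-smoothness of hard clipping.
#'
#' @param state A data frame with columns `S, T_A, T_M, L, M`.
#' @param rate Restoring rate `lambda` (>= 0).
#' @return A tibble of additive derivative contributions (columns
#'   `dS, dT_A, dT_M, dL, dM`).
#' @export
negativity_guard <- function(state, rate = 100) {
  stopifnot(rate >= 0)
  state <- as_state_df(state)
  out <- lapply(state, function(u) -rate * pmin(u, 0))
  names(out) <- paste0("d", names(state))
  tibble::as_tibble(out)
}

#' Full semi-discrete right-hand side (reference implementation)
#'
#' Combines [reaction_terms()] with the transport terms: tumour fields
#' diffuse with mobility `Delta_T * (1 - M)`, acid with unit coefficient;
#' stroma and matrix have no transport. Zero-flux boundaries are realised by
#' ghost-point reflection inside [diffusion_stencil()], and the
#' stabilisation terms (negativity guard and extinction floor, see
#' [solver_settings()]) are added. This pure-R version is the readable
#' reference for the compiled right-hand side used by [simulate_invasion()];
#' the two are held equal by the test suite.
#'
#' @param state A data frame with columns `S, T_A, T_M, L, M` matching the
#'   grid.
#' @param params An [dimensionless_params()] object.
#' @param grid A [grid_1d()] object.
#' @param stabilisation_rate Negativity-guard rate (default 100).
#' @param extinction_threshold Growth-suppression floor (default 1e-6; 0
#'   disables it).
#' @param reaction Include the reaction terms (default `TRUE`); disabling
#'   them exposes the bare transport operator.
#' @return A tibble with columns `dS, dT_A, dT_M, dL, dM`.
#' @export
assemble_rhs <- function(state, params, grid, stabilisation_rate = 100,
                         extinction_threshold = 1e-6, reaction = TRUE) {
  stopifnot(inherits(grid, "grid_1d"))
  state <- as_state_df(state)
  if (nrow(state) != grid$n_points) {
    stop("state has ", nrow(state), " rows but the grid has ",
         grid$n_points, " points")
  }
  d <- if (reaction) {
    dd <- reaction_terms(state, params)
    if (extinction_threshold > 0) {
      # gate the logistic source through the extinction floor (C1 ramp
      # between the floor and twice the floor, matching the compiled rhs)
      gate <- function(u) {
        s <- pmin(pmax(u / extinction_threshold - 1, 0), 1)
        s^2 * (3 - 2 * s)
      }
      acid_kill <- -params$delta * state$S * state$L
      dd$dS <- gate(state$S) * (dd$dS - acid_kill) + acid_kill
      dd$dT_A <- gate(state$T_A) * dd$dT_A
      dd$dT_M <- gate(state$T_M) * dd$dT_M
    }
    dd
  } else {
    tibble::as_tibble(lapply(stats::setNames(nm = c("dS", "dT_A", "dT_M",
                                                    "dL", "dM")),
                             function(nm) rep(0, nrow(state))))
  }
  Dm <- 1 - state$M
  ones <- rep(1, grid$n_points)
  d$dT_A <- d$dT_A + params$Delta_T * diffusion_stencil(state$T_A, Dm, grid$h)
  d$dT_M <- d$dT_M + params$Delta_T * diffusion_stencil(state$T_M, Dm, grid$h)
  d$dL   <- d$dL + diffusion_stencil(state$L, ones, grid$h)
  if (stabilisation_rate > 0) {
    g <- negativity_guard(state, stabilisation_rate)
    d <- tibble::as_tibble(mapply(`+`, d, g, SIMPLIFY = FALSE))
  }
  d
}

# state tibble (x,S,T_A,T_M,L,M) -> interleaved numeric vector and back
state_to_vec <- function(state) {
  as.vector(rbind(state$S, state$T_A, state$T_M, state$L, state$M))
}

vec_to_state <- function(y, x) {
  m <- matrix(y, nrow = 5)
  tibble::tibble(x = x, S = m[1, ], T_A = m[2, ], T_M = m[3, ],
                 L = m[4, ], M = m[5, ])
}

#' Integrate the invasion model
#'
#' Advances the method-of-lines system with a variable-order implicit
#' multistep (BDF) integrator at the requested tolerances and returns the
#' state at the requested snapshot times. The run is fully deterministic.
#'
#' @param init Initial state: a data frame with columns `x, S, T_A, T_M, L,
#'   M` matching `grid`, or `NULL` to build one from `ics`.
#' @param params An [dimensionless_params()] object.
#' @param grid A [grid_1d()] object.
#' @param times Strictly increasing snapshot times starting at >= 0; a
#'   leading 0 is added if absent (default `c(0, 25, 50)`).
#' @param ics An [initial_condition_spec()] used when `init` is `NULL`.
#' @param settings A [solver_settings()] object.
#' @return An `invasion_sim` object: a tibble with columns
#'   `time, x, S, T_A, T_M, L, M` (one block of rows per snapshot) carrying
#'   the parameters, grid and settings as attributes.
#' @examples
#' \donttest{
#' sim <- simulate_invasion(params = dimensionless_params(),
#'                          grid = grid_1d(100), times = c(0, 5),
#'                          settings = solver_settings(1e-8, 1e-8))
#' glance(sim)
#' }
#' @export
simulate_invasion <- function(init = NULL, params = dimensionless_params(),
                              grid = grid_1d(), times = c(0, 25, 50),
                              ics = initial_condition_spec(),
                              settings = solver_settings()) {
  stopifnot(inherits(params, "invasion_params"), inherits(grid, "grid_1d"),
            inherits(settings, "solver_settings"))
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("snapshot times must be strictly increasing and non-negative")
  }
  prepend0 <- times[1] > 0
  solve_times <- if (prepend0) c(0, times) else times
  if (is.null(init)) init <- initial_state(grid, ics)
  init <- init[order(init$x), , drop = FALSE]
  if (nrow(init) != grid$n_points) {
    stop("initial state does not match the grid")
  }
  y0 <- state_to_vec(init)
  parms <- c(grid$n_points, grid$h, params$delta, params$rho_T,
             params$Delta_T, params$rho_L, params$kappa, params$c_S,
             params$c_MA, params$c_AM, settings$stabilisation_rate,
             settings$extinction_threshold)

  if (settings$use_compiled) {
    out <- deSolve::ode(y = y0, times = solve_times, func = "invasion_derivs",
                        parms = parms, dllname = "acidinvasion",
                        initfunc = "invasion_init", method = "bdf",
                        jactype = "bandint", bandup = 8L, banddown = 8L,
                        rtol = settings$rel_tol, atol = settings$abs_tol,
                        maxsteps = settings$max_steps)
  } else {
    rhs_r <- function(t, y, p) {
      st <- vec_to_state(y, grid$x)
      d <- assemble_rhs(st, params, grid,
                        stabilisation_rate = settings$stabilisation_rate,
                        extinction_threshold =
                          settings$extinction_threshold)
      list(as.vector(rbind(d$dS, d$dT_A, d$dT_M, d$dL, d$dM)))
    }
    out <- deSolve::ode(y = y0, times = solve_times, func = rhs_r,
                        parms = NULL, method = "bdf", jactype = "bandint",
                        bandup = 8L, banddown = 8L,
                        rtol = settings$rel_tol, atol = settings$abs_tol,
                        maxsteps = settings$max_steps)
  }
  if (nrow(out) < length(solve_times) || any(!is.finite(out))) {
    reached <- out[nrow(out), 1]
    stop(sprintf("integration failed at t = %g (requested horizon %g)",
                 reached, max(solve_times)))
  }
  keep <- match(times, solve_times)
  snaps <- purrr::map(keep, function(i) {
    st <- vec_to_state(out[i, -1], grid$x)
    tibble::add_column(st, time = out[i, 1], .before = 1)
  })
  res <- dplyr::bind_rows(snaps)
  structure(res, params = params, grid = grid, settings = settings,
            class = c("invasion_sim", class(res)))
}

#' Extract one snapshot from a simulation
#'
#' @param sim An `invasion_sim` object.
#' @param time One of the snapshot times stored in `sim`.
#' @return A tibble with columns `x, S, T_A, T_M, L, M`.
#' @export
snapshot_at <- function(sim, time) {
  tt <- unique(sim$time)
  i <- which(abs(tt - time) <= 1e-9 * max(1, abs(time)))
  if (!length(i)) {
    stop("time ", time, " is not a stored snapshot (available: ",
         paste(signif(tt, 6), collapse = ", "), ")")
  }
  out <- sim[sim$time == tt[i[1]], c("x", "S", "T_A", "T_M", "L", "M")]
  tibble::as_tibble(as.data.frame(out))
}

#' @export
print.invasion_sim <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<invasion_sim> %d snapshot(s) at t = %s on %d grid points\n",
              length(unique(x$time)),
              paste(signif(unique(x$time), 6), collapse = ", "),
              g$n_points))
  NextMethod()
}
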