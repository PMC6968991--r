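#' Long-horizon single-population experiment
#'
#' Integrates the model with only one tumour phenotype present and reports
#' the front-position time series and the final (stalled) front. In
#' isolation neither phenotype can invade: the acid-producers advance
#' through the partially open matrix until they meet the intact-matrix wall,
#' while the matrix-degraders are confined by the stroma, which they cannot
#' remove.
#'
#' @param which `"T_A"` or `"T_M"`: the phenotype present.
#' @param params,grid,ics,settings Model configuration; the presence flags
#'   in `ics` are overridden by `which`.
#' @param t_end Final time (default 10000).
#' @param times Snapshot times; defaults to a sparse log-like schedule up to
#'   `t_end`.
#' @param front_eps Front detection threshold.
#' @param stall_window Final-interval length over which a displacement below
#'   `stall_displacement` counts as stalled (default 0.1 * t_end).
#' @param stall_displacement Displacement threshold (default 0.01).
#' @return An object of class `single_population_run`: a list with `sim`,
#'   `front_series` (tibble `time`, `front`), `stall_position` (front at
#'   `t_end`), `stalled` (logical) and `which`.
#' @export
run_single_population <- function(which = c("T_A", "T_M"),
                                  params = dimensionless_params(),
                                  t_end = 10000, grid = grid_1d(),
                                  ics = initial_condition_spec(),
                                  settings = solver_settings(),
                                  times = NULL, front_eps = 1e-2,
                                  stall_window = 0.1 * t_end,
                                  stall_displacement = 0.01) {
  which <- match.arg(which)
  if (is.null(times)) {
    times <- unique(c(0, 10, 25, 50, 100, 250, 500, 1000, 2500, 5000,
                      t_end - stall_window, t_end))
    times <- sort(times[times >= 0 & times <= t_end])
  }
  ics$include_TA <- which == "T_A"
  ics$include_TM <- which == "T_M"
  if (!ics$include_TA && !ics$include_TM) {
    stop("invalid experiment: at least one phenotype must be present")
  }
  sim <- simulate_invasion(params = params, grid = grid, times = times,
                           ics = ics, settings = settings)
  fronts <- purrr::map_dbl(times, function(tt) {
    front_position(snapshot_at(sim, tt), species = which, eps = front_eps)
  })
  series <- tibble::tibble(time = times, front = fronts)
  nt <- length(times)
  stall_position <- fronts[nt]
  stalled <- is.na(fronts[nt]) || is.na(fronts[nt - 1]) ||
    abs(fronts[nt] - fronts[nt - 1]) < stall_displacement
  structure(list(which = which, sim = sim, front_series = series,
                 stall_position = stall_position, stalled = stalled),
            class = "single_population_run")
}

#' @export
print.single_population_run <- function(x, ...) {
  cat(sprintf("<single_population_run> %s only: front %s at t = %g (%s)\n",
              x$which, signif(x$stall_position, 4),
              max(x$front_series$time),
              if (x$stalled) "stalled" else "still advancing"))
  invisible(x)
}

# run one (c_MA, c_AM) combination and measure the end state
run_one_combination <- function(c_MA, c_AM, params, t_end, grid, ics,
                                settings, front_eps) {
  p <- params
  p$c_MA <- c_MA
  p$c_AM <- c_AM
  times <- unique(sort(c(0, t_end / 2, t_end)))
  sim <- simulate_invasion(params = p, grid = grid, times = times,
                           ics = ics, settings = settings)
  fin <- snapshot_at(sim, t_end)
  int_TA <- population_size(fin, "T_A")
  int_TM <- population_size(fin, "T_M")
  tibble::tibble(
    c_MA = c_MA, c_AM = c_AM,
    front_either = front_position(fin, "either", eps = front_eps),
    front_max_rate = front_position(fin, "either", method = "max_rate",
                                    eps = front_eps, params = p,
                                    grid = grid),
    mass = tumour_mass(fin),
    int_TA = int_TA, int_TM = int_TM,
    disregard_TA = int_TA < 0.1,
    disregard_TM = int_TM < 0.1,
    regime = classify_regime(c_MA, c_AM),
    error = NA_character_
  )
}

#' Competition-parameter sweep
#'
#' Simulates invasion for every combination of the two inter-phenotype
#' competition coefficients on a grid, and records for each: the combined
#' front position (threshold and derivative-extremum constructions), the
#' total tumour mass, per-species integrals with disregard flags (integral
#' below 0.1), and the predicted regime label. Failures of individual runs
#' are recorded in the `error` column instead of aborting the sweep, and
#' results are independent of evaluation order.
#'
#' @param c_MA,c_AM Coefficient values; the sweep covers their Cartesian
#'   product (defaults: 20 equally spaced values on `[0, 2]` each).
#' @param params,grid,ics,settings Model configuration (competition entries
#'   of `params` are overridden pointwise).
#' @param t_end Final time (default 50).
#' @param front_eps Front threshold.
#' @param progress Print one line per combination.
#' @return A tibble of class `invasion_sweep`, one row per combination.
#' @export
run_competition_sweep <- function(c_MA = seq(0, 2, length.out = 20),
                                  c_AM = seq(0, 2, length.out = 20),
                                  params = dimensionless_params(),
                                  t_end = 50, grid = grid_1d(),
                                  ics = initial_condition_spec(),
                                  settings = solver_settings(),
                                  front_eps = 1e-2, progress = FALSE) {
  if (!length(c_MA) || !length(c_AM)) stop("empty competition grid")
  combos <- tidyr::expand_grid(c_MA = c_MA, c_AM = c_AM)
  rows <- purrr::pmap(combos, function(c_MA, c_AM) {
    if (progress) message(sprintf("sweep: c_MA = %.3g, c_AM = %.3g",
                                  c_MA, c_AM))
    tryCatch(
      run_one_combination(c_MA, c_AM, params, t_end, grid, ics, settings,
                          front_eps),
      error = function(e) tibble::tibble(
        c_MA = c_MA, c_AM = c_AM, front_either = NA_real_,
        front_max_rate = NA_real_, mass = NA_real_, int_TA = NA_real_,
        int_TM = NA_real_, disregard_TA = NA, disregard_TM = NA,
        regime = classify_regime(c_MA, c_AM),
        error = conditionMessage(e))
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, t_end = t_end,
            class = c("invasion_sweep", class(out)))
}

#' Snapshot experiment for one competition combination
#'
#' Runs one `(c_MA, c_AM)` combination, stores snapshots, and classifies the
#' qualitative outcome from species survival and front motion. The
#' documented classification constants are: a species is extinct when its
#' integral at the final time is below 1e-3; the front has halted when its
#' displacement over the final 10 time units is below 0.01.
#'
#' Outcome labels: `mixed_invasion` (both phenotypes survive and the front
#' advances, inter-species competition below the intra-species level),
#' `unstable_mixed_front` (as before but with both coefficients above 1, a
#' front that perturbations destabilise), `encapsulation` (acid-producers
#' eliminated, invasion halts), `transient_invasion` (matrix-degraders
#' eliminated; advance continues only temporarily), `stalled_front`
#' (both survive but the front no longer moves).
#'
#' @param c_MA,c_AM Competition coefficients.
#' @param params,grid,ics,settings Model configuration.
#' @param times Snapshot times; the last two must bracket the final 10 time
#'   units for the halt test (default `c(0, 25, 40, 50)`).
#' @param front_eps Front threshold.
#' @return A list of class `snapshot_experiment`: `sim`, `outcome`,
#'   `fronts` (tibble `time`, `front`), `extinct_TA`, `extinct_TM`,
#'   `halted`.
#' @export
run_snapshot_experiment <- function(c_MA, c_AM,
                                    params = dimensionless_params(),
                                    grid = grid_1d(),
                                    ics = initial_condition_spec(),
                                    settings = solver_settings(),
                                    times = c(0, 25, 40, 50),
                                    front_eps = 1e-2) {
  p <- params
  p$c_MA <- c_MA
  p$c_AM <- c_AM
  sim <- simulate_invasion(params = p, grid = grid, times = times,
                           ics = ics, settings = settings)
  fronts <- purrr::map_dbl(times, function(tt) {
    front_position(snapshot_at(sim, tt), "either", eps = front_eps)
  })
  fin <- snapshot_at(sim, max(times))
  extinct_TA <- population_size(fin, "T_A") < 1e-3
  extinct_TM <- population_size(fin, "T_M") < 1e-3
  nt <- length(times)
  last_disp <- fronts[nt] - fronts[nt - 1]
  dt_last <- times[nt] - times[nt - 1]
  halted <- is.na(last_disp) || (last_disp / dt_last * 10 < 0.01)
  advanced <- !is.na(fronts[nt]) && !is.na(fronts[1]) &&
    fronts[nt] - fronts[1] > 0.05
  outcome <- if (extinct_TA) {
    "encapsulation"
  } else if (extinct_TM) {
    "transient_invasion"
  } else if (!halted && advanced) {
    if (c_MA > 1 && c_AM > 1) "unstable_mixed_front" else "mixed_invasion"
  } else {
    "stalled_front"
  }
  structure(list(sim = sim, outcome = outcome,
                 fronts = tibble::tibble(time = times, front = fronts),
                 extinct_TA = extinct_TA, extinct_TM = extinct_TM,
                 halted = halted),
            class = "snapshot_experiment")
}

#' @export
print.snapshot_experiment <- function(x, ...) {
  cat(sprintf("<snapshot_experiment> outcome: %s (front %s -> %s)\n",
              x$outcome, signif(x$fronts$front[1], 4),
              signif(x$fronts$front[nrow(x$fronts)], 4)))
  invisible(x)
}

# overlap of the two phenotype profiles: 1 = perfectly mixed, 0 = disjoint
mixing_index <- function(state) {
  state <- as.data.frame(state)
  tot <- pracma::trapz(state$x, state$T_A + state$T_M)
  if (tot < 1e-8) return(NA_real_)
  pracma::trapz(state$x, pmin(state$T_A, state$T_M)) / (tot / 2)
}

#' Front-instability (perturbation) experiment
#'
#' In the bistable regime (both competition coefficients above 1) two
#' identically seeded phenotypes invade together, but the mixed front is
#' unstable: any asymmetry sends the populations toward spatially separated
#' (parapatric) configurations. This driver runs an unperturbed and a
#' perturbed variant with identical solver settings and compares them.
#'
#' Perturbation modes: `"multiplicative-noise"` multiplies each phenotype's
#' initial profile by `1 + amplitude * U(-1, 1)` (independent draws per grid
#' point and species, seeded); `"spatial-offset"` seeds the matrix-degraders
#' slightly behind the acid-producers (`sigma_tumour - offset`).
#'
#' Separation is judged by the overlap of the two phenotype profiles at the
#' final time: `mixing = integral of min(T_A, T_M) / (mass / 2)`; the
#' populations count as spatially separated when both survive and mixing
#' falls below 0.2 (documented constant).
#'
#' @param c_MA,c_AM Competition coefficients (defaults 1.7, 1.7).
#' @param amplitude Noise amplitude (default 1e-2).
#' @param mode `"multiplicative-noise"` or `"spatial-offset"`.
#' @param offset Offset distance for the spatial-offset mode (default 0.02).
#' @param seed RNG seed, recorded in the output.
#' @param params,grid,ics,settings,times,front_eps As elsewhere.
#' @return A list of class `perturbation_experiment` with both simulations
#'   and a one-row `summary` tibble (mixing indices, fronts, `separated`,
#'   `front_lag` = unperturbed front minus perturbed front at the final
#'   time, seed and mode).
#' @export
run_perturbation_experiment <- function(c_MA = 1.7, c_AM = 1.7,
                                        amplitude = 1e-2,
                                        mode = c("multiplicative-noise",
                                                 "spatial-offset"),
                                        offset = 0.02, seed = 1L,
                                        params = dimensionless_params(),
                                        grid = grid_1d(),
                                        ics = initial_condition_spec(),
                                        settings = solver_settings(),
                                        times = c(0, 25, 40, 50),
                                        front_eps = 1e-2) {
  mode <- match.arg(mode)
  if (amplitude < 0) stop("amplitude must be >= 0")
  p <- params
  p$c_MA <- c_MA
  p$c_AM <- c_AM

  base_init <- initial_state(grid, ics)
  pert_init <- base_init
  if (mode == "multiplicative-noise") {
    set.seed(seed)
    n <- grid$n_points
    pert_init$T_A <- pmax(0, base_init$T_A *
                            (1 + amplitude * stats::runif(n, -1, 1)))
    pert_init$T_M <- pmax(0, base_init$T_M *
                            (1 + amplitude * stats::runif(n, -1, 1)))
  } else {
    if (offset >= ics$sigma_tumour) stop("offset must be < sigma_tumour")
    pert_init$T_M <- regularised_step(
      grid$x, ics$sigma_tumour - offset + ics$omega, ics$omega)
  }

  sim0 <- simulate_invasion(init = base_init, params = p, grid = grid,
                            times = times, settings = settings)
  sim1 <- simulate_invasion(init = pert_init, params = p, grid = grid,
                            times = times, settings = settings)
  fin0 <- snapshot_at(sim0, max(times))
  fin1 <- snapshot_at(sim1, max(times))
  mix0 <- mixing_index(fin0)
  mix1 <- mixing_index(fin1)
  alive1 <- population_size(fin1, "T_A") > 1e-3 &&
    population_size(fin1, "T_M") > 1e-3
  f0 <- front_position(fin0, "either", eps = front_eps)
  f1 <- front_position(fin1, "either", eps = front_eps)
  summary <- tibble::tibble(
    mode = mode, amplitude = amplitude, seed = as.integer(seed),
    mixing_unperturbed = mix0, mixing_perturbed = mix1,
    front_unperturbed = f0, front_perturbed = f1,
    front_lag = f0 - f1,
    separated = alive1 && !is.na(mix1) && mix1 < 0.2
  )
  structure(list(unperturbed = sim0, perturbed = sim1, summary = summary),
            class = "perturbation_experiment")
}

#' Matrix-degradation (kappa) sensitivity study
#'
#' Repeats the competition sweep for several matrix-degradation rates and
#' reports, per rate, an asymmetry statistic of the front map: the mean of
#' `front(a, b) - front(b, a)` over unordered pairs `a < b` drawn from the
#' sub-unit quadrant. A nonzero value means the invaded distance responds
#' differently to competitiveness of the acid-producers than of the
#' matrix-degraders, and its dependence on kappa identifies matrix
#' remodelling as the bottleneck.
#'
#' @param kappa_values Degradation rates to test (default `c(5, 10, 20)`).
#' @param c_values Competition values for the reduced sweep grid (default
#'   `c(0.25, 0.5, 0.75)`, all below 1).
#' @param params,t_end,grid,ics,settings,front_eps As for
#'   [run_competition_sweep()].
#' @return A list of class `kappa_sensitivity`: `sweeps` (named list of
#'   sweep tibbles) and `asymmetry` (tibble `kappa`, `asymmetry`).
#' @export
run_kappa_sensitivity <- function(kappa_values = c(5, 10, 20),
                                  c_values = c(0.25, 0.5, 0.75),
                                  params = dimensionless_params(),
                                  t_end = 50, grid = grid_1d(),
                                  ics = initial_condition_spec(),
                                  settings = solver_settings(),
                                  front_eps = 1e-2) {
  if (any(kappa_values < 0)) stop("kappa values must be >= 0")
  sweeps <- purrr::map(kappa_values, function(k) {
    p <- params
    p$kappa <- k
    run_competition_sweep(c_MA = c_values, c_AM = c_values, params = p,
                          t_end = t_end, grid = grid, ics = ics,
                          settings = settings, front_eps = front_eps)
  })
  names(sweeps) <- paste0("kappa_", kappa_values)
  asym <- purrr::map2_dbl(sweeps, kappa_values, function(sw, k) {
    pairs <- tidyr::expand_grid(a = c_values, b = c_values)
    pairs <- pairs[pairs$a < pairs$b, ]
    if (!nrow(pairs)) return(NA_real_)
    diffs <- purrr::pmap_dbl(pairs, function(a, b) {
      fa <- sw$front_either[abs(sw$c_MA - a) < 1e-12 &
                              abs(sw$c_AM - b) < 1e-12]
      fb <- sw$front_either[abs(sw$c_MA - b) < 1e-12 &
                              abs(sw$c_AM - a) < 1e-12]
      if (!length(fa) || !length(fb)) return(NA_real_)
      fa - fb
    })
    mean(diffs, na.rm = TRUE)
  })
  structure(list(sweeps = sweeps,
                 asymmetry = tibble::tibble(kappa = kappa_values,
                                            asymmetry = unname(asym))),
            class = "kappa_sensitivity")
}
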