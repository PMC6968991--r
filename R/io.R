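config_defaults <- function() {
  list(
    # dimensionless parameters
    delta = 12.5, rho_T = 1, Delta_T = 4e-5, rho_L = 70, kappa = 10,
    c_S = 1.5, c_MA = 0, c_AM = 0,
    # initial conditions
    sigma_tissue = 0.2, sigma_tumour = 0.1, omega = 0.1,
    include_TA = TRUE, include_TM = TRUE,
    # grid
    n_points = 200L, domain_length = 1,
    # solver
    rel_tol = 1e-10, abs_tol = 1e-10, stabilisation_rate = 100,
    snapshot_times = c(0, 25, 50), t_end = 50,
    # experiment selection and experiment-specific keys
    experiment = "simulate", which_population = "T_A",
    sweep_points = 20L, c_values = c(0.25, 0.5, 0.75),
    kappa_values = c(5, 10, 20),
    perturb_amplitude = 1e-2, perturb_mode = "multiplicative-noise",
    offset_distance = 0.02, front_eps = 1e-2,
    # bookkeeping
    outdir = "invasion-run", seed = 1L
  )
}

#' Load a run configuration
#'
#' Reads a flat key-value YAML file, checks every key against the documented
#' schema (unknown keys are an error naming the key), type-checks the
#' values, and fills in defaults for absent keys. An empty (or missing-key)
#' file therefore resolves to the reference parameterisation: Table of
#' defaults in [dimensionless_params()], a 200-point unit grid, tolerances
#' `1e-10`.
#'
#' @param path Path to the YAML configuration file.
#' @return A list of class `run_config` with every key resolved; the names
#'   of keys that were defaulted are in `attr(, "defaulted")`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("configuration must be a key-value mapping")
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (k in names(user)) {
    v <- user[[k]]
    d <- defaults[[k]]
    if (is.numeric(d) && !is.numeric(v)) {
      stop("configuration key '", k, "' must be numeric")
    }
    if (is.logical(d) && !is.logical(v)) {
      stop("configuration key '", k, "' must be logical")
    }
    if (is.character(d) && !is.character(v)) {
      stop("configuration key '", k, "' must be a string")
    }
    if (is.numeric(d) && length(d) == 1L &&
        k %in% c("delta", "rho_T", "Delta_T", "rho_L", "kappa", "c_S",
                 "c_MA", "c_AM", "omega", "rel_tol", "abs_tol",
                 "stabilisation_rate", "front_eps", "perturb_amplitude",
                 "t_end", "n_points", "domain_length") && any(v < 0)) {
      stop("configuration key '", k, "' is out of range (negative)")
    }
    cfg[[k]] <- v
  }
  structure(cfg, defaulted = setdiff(names(defaults), names(user)),
            class = "run_config")
}

#' @rdname load_config
#' @param cfg A `run_config` object.
#' @export
config_params <- function(cfg) {
  dimensionless_params(delta = cfg$delta, rho_T = cfg$rho_T,
                       Delta_T = cfg$Delta_T, rho_L = cfg$rho_L,
                       kappa = cfg$kappa, c_S = cfg$c_S,
                       c_MA = cfg$c_MA, c_AM = cfg$c_AM)
}

#' @rdname load_config
#' @export
config_grid <- function(cfg) grid_1d(cfg$n_points, cfg$domain_length)

#' @rdname load_config
#' @export
config_ics <- function(cfg) {
  initial_condition_spec(sigma_tissue = cfg$sigma_tissue,
                         sigma_tumour = cfg$sigma_tumour,
                         omega = cfg$omega, include_TA = cfg$include_TA,
                         include_TM = cfg$include_TM)
}

#' @rdname load_config
#' @export
config_settings <- function(cfg) {
  solver_settings(rel_tol = cfg$rel_tol, abs_tol = cfg$abs_tol,
                  stabilisation_rate = cfg$stabilisation_rate)
}

#' Write a trajectory to a run directory
#'
#' One plain tab-separated table per snapshot (columns
#' `x, S, T_A, T_M, L, M`) plus a `manifest.yaml` recording the parameters,
#' grid, solver settings and snapshot times, so that a run directory is
#' self-describing and re-executable.
#'
#' @param sim An `invasion_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(sim, dir) {
  stopifnot(inherits(sim, "invasion_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- attr(sim, "params")
  grid <- attr(sim, "grid")
  settings <- attr(sim, "settings")
  times <- unique(sim$time)
  manifest <- list(
    package = "acidinvasion",
    params = unclass(params),
    grid = list(n_points = grid$n_points, length = grid$length),
    settings = list(rel_tol = settings$rel_tol, abs_tol = settings$abs_tol,
                    stabilisation_rate = settings$stabilisation_rate),
    times = as.numeric(times)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"),
                   precision = 17L)
  for (i in seq_along(times)) {
    snap <- snapshot_at(sim, times[i])
    readr::write_tsv(snap, file.path(dir, sprintf("snapshot_%03d.tsv", i)),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Read a trajectory back from a run directory
#'
#' @param dir A directory written by [write_trajectory()].
#' @return An `invasion_sim` object equal to the original up to the text
#'   representation precision of the snapshot tables.
#' @export
read_trajectory <- function(dir) {
  mpath <- file.path(dir, "manifest.yaml")
  if (!file.exists(mpath)) stop("no manifest.yaml in ", dir)
  manifest <- yaml::read_yaml(mpath)
  need <- c("params", "grid", "settings", "times")
  if (!all(need %in% names(manifest))) {
    stop("corrupt manifest in ", dir, ": missing ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  }
  params <- do.call(dimensionless_params, manifest$params)
  grid <- grid_1d(manifest$grid$n_points, manifest$grid$length)
  settings <- solver_settings(rel_tol = manifest$settings$rel_tol,
                              abs_tol = manifest$settings$abs_tol,
                              stabilisation_rate =
                                manifest$settings$stabilisation_rate)
  times <- as.numeric(manifest$times)
  cols <- c("x", "S", "T_A", "T_M", "L", "M")
  snaps <- purrr::map2(seq_along(times), times, function(i, tt) {
    fpath <- file.path(dir, sprintf("snapshot_%03d.tsv", i))
    if (!file.exists(fpath)) stop("corrupt trajectory: missing ", fpath)
    snap <- readr::read_tsv(fpath, show_col_types = FALSE, progress = FALSE)
    if (!identical(names(snap), cols) || nrow(snap) != grid$n_points) {
      stop("corrupt snapshot table: ", fpath)
    }
    tibble::add_column(snap, time = tt, .before = 1)
  })
  res <- dplyr::bind_rows(snaps)
  structure(res, params = params, grid = grid, settings = settings,
            class = c("invasion_sim", class(res)))
}
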