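#' Dimensionless model parameters
#'
#' The rescaled invasion model is governed by eight dimensionless groups:
#' the acid-kill strength `delta`, the tumour/stroma growth-rate ratio
#' `rho_T`, the tumour/acid diffusivity ratio `Delta_T`, the acid turnover
#' rate `rho_L`, the matrix-degradation rate `kappa`, the stromal
#' competition coefficient `c_S`, and the two inter-phenotype Lotka-Volterra
#' competition coefficients `c_MA` (effect of the matrix-degraders on the
#' acid-producers) and `c_AM` (the converse). Defaults are the reference
#' parameterisation used throughout the experiment drivers.
#'
#' The analytical stability results consumed downstream assume `delta > 1`
#' and `c_S > 1`; the constructor warns (but does not refuse) when either is
#' violated, because the model itself remains well posed.
#'
#' @param delta Acid-induced stromal death strength (default 12.5).
#' @param rho_T Tumour/stroma growth-rate ratio (default 1).
#' @param Delta_T Tumour/acid diffusivity ratio (default 4e-5).
#' @param rho_L Acid turnover rate (default 70).
#' @param kappa Matrix-degradation rate (default 10).
#' @param c_S Competition of stroma on both tumour phenotypes (default 1.5).
#' @param c_MA Competition of the matrix-degraders on the acid-producers
#'   (default 0).
#' @param c_AM Competition of the acid-producers on the matrix-degraders
#'   (default 0).
#' @return An object of class `invasion_params`: a named list of the eight
#'   groups.
#' @examples
#' dimensionless_params()
#' dimensionless_params(c_MA = 1.2, c_AM = 0.7)
#' @export
dimensionless_params <- function(delta = 12.5, rho_T = 1, Delta_T = 4e-5,
                                 rho_L = 70, kappa = 10, c_S = 1.5,
                                 c_MA = 0, c_AM = 0) {
  p <- list(delta = delta, rho_T = rho_T, Delta_T = Delta_T, rho_L = rho_L,
            kappa = kappa, c_S = c_S, c_MA = c_MA, c_AM = c_AM)
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v < 0, logical(1))
  if (any(bad)) {
    stop("invalid dimensionless parameter(s): ",
         paste(names(p)[bad], collapse = ", "),
         " (each must be a single finite non-negative number)")
  }
  if (delta <= 1) {
    warning("delta <= 1: acid cannot eradicate stroma; ",
            "stability classifications that assume delta > 1 do not apply")
  }
  if (c_S <= 1) {
    warning("c_S <= 1: stroma does not competitively exclude tumour cells; ",
            "stability classifications that assume c_S > 1 do not apply")
  }
  structure(p, class = "invasion_params")
}

#' @export
print.invasion_params <- function(x, ...) {
  cat("<invasion_params>\n")
  cat(sprintf("  delta = %g, rho_T = %g, Delta_T = %g, rho_L = %g, kappa = %g\n",
              x$delta, x$rho_T, x$Delta_T, x$rho_L, x$kappa))
  cat(sprintf("  c_S = %g, c_MA = %g, c_AM = %g\n", x$c_S, x$c_MA, x$c_AM))
  invisible(x)
}

#' Dimensional model parameters
#'
#' Container for the dimensional rates and capacities of the original
#' (unscaled) model. The two tumour phenotypes are assumed biologically
#' identical apart from acid production and matrix degradation: one growth
#' rate `r_T`, one diffusivity `D_T`, and one carrying capacity `K` shared
#' with the stroma.
#'
#' @param r_S Stromal growth rate (1/time).
#' @param K Shared carrying capacity of stroma and tumour (cells/volume).
#' @param d_S Acid-induced stromal death coefficient.
#' @param r_T Tumour growth rate (1/time).
#' @param D_T Tumour diffusivity (length^2/time).
#' @param r_L Acid production rate.
#' @param d_L Acid removal rate (1/time).
#' @param D_L Acid diffusivity (length^2/time).
#' @param d_M Matrix degradation coefficient.
#' @param K_M Matrix density at which tumour motility ceases.
#' @param c_S,c_MA,c_AM Competition coefficients (already dimensionless;
#'   passed through by [nondimensionalise()]).
#' @return An object of class `dimensional_params`.
#' @export
dimensional_params <- function(r_S, K, d_S, r_T, D_T, r_L, d_L, D_L,
                               d_M, K_M, c_S = 1.5, c_MA = 0, c_AM = 0) {
  p <- list(r_S = r_S, K = K, d_S = d_S, r_T = r_T, D_T = D_T, r_L = r_L,
            d_L = d_L, D_L = D_L, d_M = d_M, K_M = K_M,
            c_S = c_S, c_MA = c_MA, c_AM = c_AM)
  core <- setdiff(names(p), c("c_S", "c_MA", "c_AM"))
  bad <- vapply(p[core], function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v <= 0, logical(1))
  if (any(bad)) {
    stop("invalid dimensional parameter(s): ",
         paste(core[bad], collapse = ", "),
         " (rates, diffusivities and capacities must be strictly positive)")
  }
  structure(p, class = "dimensional_params")
}

#' Map dimensional parameters to the dimensionless groups
#'
#' Applies the standard rescaling: time by the stromal growth rate, space by
#' the acid diffusion length, densities by the carrying capacities. The
#' resulting groups are
#' \deqn{\delta = \frac{d_S r_L K}{d_L r_S},\quad \rho_T = \frac{r_T}{r_S},
#'   \quad \Delta_T = \frac{D_T}{D_L},\quad \rho_L = \frac{d_L}{r_S},
#'   \quad \kappa = \frac{d_M K}{r_S}.}
#' The competition coefficients are already dimensionless and pass through
#' unchanged.
#'
#' @param dp A [dimensional_params()] object.
#' @return An [dimensionless_params()] object.
#' @export
nondimensionalise <- function(dp) {
  stopifnot(inherits(dp, "dimensional_params"))
  dimensionless_params(
    delta   = dp$d_S * dp$r_L * dp$K / (dp$d_L * dp$r_S),
    rho_T   = dp$r_T / dp$r_S,
    Delta_T = dp$D_T / dp$D_L,
    rho_L   = dp$d_L / dp$r_S,
    kappa   = dp$d_M * dp$K / dp$r_S,
    c_S     = dp$c_S,
    c_MA    = dp$c_MA,
    c_AM    = dp$c_AM
  )
}
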