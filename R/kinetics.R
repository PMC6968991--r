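#' Pointwise reaction kinetics of the non-dimensional model
#'
#' Evaluates the spatially local (reaction) part of the five coupled
#' equations at each row of `state`:
#' \deqn{dS/dt = S(1-S) - \delta S L}
#' \deqn{dT_A/dt = \rho_T T_A (1 - c_S S - T_A - c_{MA} T_M)}
#' \deqn{dT_M/dt = \rho_T T_M (1 - c_S S - c_{AM} T_A - T_M)}
#' \deqn{dL/dt = \rho_L (T_A - L)}
#' \deqn{dM/dt = -\kappa T_M M}
#' Diffusion is deliberately excluded; it is added by the solver (see
#' [assemble_rhs()]), so that the homogeneous steady-state analysis can reuse
#' the pure kinetics.
#'
#' @param state A data frame with numeric columns `S`, `T_A`, `T_M`, `L`,
#'   `M` (one row per location, or a single row for a point evaluation).
#' @param params An [dimensionless_params()] object.
#' @return A tibble with columns `dS`, `dT_A`, `dT_M`, `dL`, `dM`, one row
#'   per input row.
#' @examples
#' p <- dimensionless_params()
#' healthy <- data.frame(S = 1, T_A = 0, T_M = 0, L = 0, M = 0.5)
#' reaction_terms(healthy, p)  # all zero: the healthy-tissue equilibrium
#' @export
reaction_terms <- function(state, params) {
  stopifnot(inherits(params, "invasion_params"))
  state <- as_state_df(state)
  S <- state$S; T_A <- state$T_A; T_M <- state$T_M; L <- state$L; M <- state$M
  if (!all(is.finite(c(S, T_A, T_M, L, M)))) {
    stop("non-finite state values passed to reaction_terms()")
  }
  tibble::tibble(
    dS   = S * (1 - S) - params$delta * S * L,
    dT_A = params$rho_T * T_A * (1 - params$c_S * S - T_A - params$c_MA * T_M),
    dT_M = params$rho_T * T_M * (1 - params$c_S * S - params$c_AM * T_A - T_M),
    dL   = params$rho_L * (T_A - L),
    dM   = -params$kappa * T_M * M
  )
}

#' Jacobian of the reaction kinetics at a state point
#'
#' Exact partial derivatives of [reaction_terms()] with respect to
#' `(S, T_A, T_M, L, M)`, coded analytically. This is the matrix whose
#' eigenvalues decide the linear stability of the homogeneous steady states;
#' note the structural property that the `M` column vanishes identically
#' wherever `T_M = 0` (nothing then responds to a matrix perturbation),
#' producing a zero eigenvalue for every matrix-retaining equilibrium.
#'
#' @param state A one-row data frame (or named list/vector) with entries
#'   `S`, `T_A`, `T_M`, `L`, `M`.
#' @param params An [dimensionless_params()] object.
#' @return A 5x5 numeric matrix with rows/columns named
#'   `S, T_A, T_M, L, M`.
#' @export
kinetics_jacobian <- function(state, params) {
  stopifnot(inherits(params, "invasion_params"))
  s <- as.list(state)
  S <- s$S; T_A <- s$T_A; T_M <- s$T_M; L <- s$L; M <- s$M
  stopifnot(all(is.finite(c(S, T_A, T_M, L, M))))
  rT <- params$rho_T
  J <- matrix(0, 5, 5, dimnames = list(c("S", "T_A", "T_M", "L", "M"),
                                       c("S", "T_A", "T_M", "L", "M")))
  J["S", "S"] <- 1 - 2 * S - params$delta * L
  J["S", "L"] <- -params$delta * S

  J["T_A", "S"]   <- -rT * T_A * params$c_S
  J["T_A", "T_A"] <- rT * (1 - params$c_S * S - 2 * T_A - params$c_MA * T_M)
  J["T_A", "T_M"] <- -rT * T_A * params$c_MA

  J["T_M", "S"]   <- -rT * T_M * params$c_S
  J["T_M", "T_A"] <- -rT * T_M * params$c_AM
  J["T_M", "T_M"] <- rT * (1 - params$c_S * S - params$c_AM * T_A - 2 * T_M)

  J["L", "T_A"] <- params$rho_L
  J["L", "L"]   <- -params$rho_L

  J["M", "T_M"] <- -params$kappa * M
  J["M", "M"]   <- -params$kappa * T_M
  J
}

# Coerce a state to a data frame with the five field columns, in order.
as_state_df <- function(state) {
  if (is.numeric(state) && !is.null(names(state))) {
    state <- as.data.frame(as.list(state))
  }
  state <- as.data.frame(state)
  need <- c("S", "T_A", "T_M", "L", "M")
  missing <- setdiff(need, names(state))
  if (length(missing)) {
    stop("state is missing field column(s): ", paste(missing, collapse = ", "))
  }
  state[need]
}
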