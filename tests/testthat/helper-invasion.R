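# shared fixtures and independent oracles, built in code

fast_settings <- function(...) solver_settings(rel_tol = 1e-8,
                                               abs_tol = 1e-8, ...)

default_params <- function(...) {
  suppressWarnings(dimensionless_params(...))
}

# a random non-negative state on n points, reproducible
random_state <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    x = seq(0, 1, length.out = n),
    S = runif(n), T_A = runif(n), T_M = runif(n),
    L = runif(n), M = runif(n)
  )
}

# independent oracle: dense matrix of the variable-diffusion operator on the
# interior (rows 2..n-1), assembled entry by entry from the stencil weights
stencil_operator_matrix <- function(D, h) {
  n <- length(D)
  A <- matrix(0, n, n)
  for (r in 2:(n - 1)) {
    A[r, r - 1] <- (D[r - 1] + D[r]) / (2 * h^2)
    A[r, r]     <- -(D[r - 1] + 2 * D[r] + D[r + 1]) / (2 * h^2)
    A[r, r + 1] <- (D[r] + D[r + 1]) / (2 * h^2)
  }
  A
}

# independent oracle: central finite differences of the reaction kinetics
fd_jacobian <- function(state, params, eps = 1e-7) {
  fields <- c("S", "T_A", "T_M", "L", "M")
  J <- matrix(0, 5, 5, dimnames = list(fields, fields))
  for (j in seq_along(fields)) {
    up <- as.list(state); dn <- as.list(state)
    up[[fields[j]]] <- up[[fields[j]]] + eps
    dn[[fields[j]]] <- dn[[fields[j]]] - eps
    fu <- unlist(reaction_terms(as.data.frame(up), params))
    fd <- unlist(reaction_terms(as.data.frame(dn), params))
    J[, j] <- (fu - fd) / (2 * eps)
  }
  J
}

# Newton iteration on the pure kinetics, used by the exhaustiveness search
newton_equilibrium <- function(start, params, tol = 1e-12, maxit = 40) {
  x <- start
  fields <- c("S", "T_A", "T_M", "L", "M")
  for (i in seq_len(maxit)) {
    st <- stats::setNames(as.list(x), fields)
    f <- unlist(reaction_terms(as.data.frame(st), params))
    if (max(abs(f)) < tol) return(x)
    J <- kinetics_jacobian(st, params)
    dx <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) return(NULL)
    x <- x - dx
    if (any(abs(x) > 50)) return(NULL)
  }
  NULL
}
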