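#' Homogeneous steady states of the invasion kinetics
#'
#' Enumerates the spatially homogeneous equilibria SS0-SS6 of the reaction
#' kinetics in closed form and classifies their linear stability from the
#' eigenvalues of the analytic Jacobian ([kinetics_jacobian()]).
#'
#' The states are, writing `(S, T_A, T_M, L, M)`:
#' * SS0 `(1, 0, 0, 0, M*)` - healthy tissue (matrix level arbitrary);
#' * SS1 `(0, 1, 0, 1, M*)` - acid-producer monoculture;
#' * SS2 `(0, 0, 1, 0, 0)` - matrix-degrader monoculture;
#' * SS3 `(0, (1-c_MA)/q, (1-c_AM)/q, (1-c_MA)/q, 0)` with
#'   `q = 1 - c_MA*c_AM` - tumour-phenotype coexistence, stroma and matrix
#'   eradicated;
#' * SS4 `((1-delta)/p, (1-c_S)/p, 0, (1-c_S)/p, M*)` with
#'   `p = 1 - c_S*delta` - acid-producers coexisting with stroma;
#' * SS5 `(1, 0, 1-c_S, 0, 0)` - matrix-degraders with stroma (never
#'   feasible when `c_S > 1`);
#' * SS6 - three-population coexistence; at `(c_MA, c_AM) = (1, 1)` this is
#'   a one-parameter family parameterised by `T_A`, elsewhere a single
#'   rational-form state.
#'
#' States that retain matrix (SS0, SS1, SS4) have a structurally free matrix
#' component: any `M* in [0, 1]` is admissible, and the `M` direction always
#' carries a zero eigenvalue (degrading cells are absent, so perturbations
#' of the matrix neither grow nor decay). Such states are at best marginal
#' overall; `stability_non_ecm` reports the classification restricted to the
#' `(S, T_A, T_M, L)` subspace, which is the scientifically relevant label.
#'
#' SS3 is undefined on the degenerate line `c_MA * c_AM = 1` (its
#' denominator vanishes); there it is reported infeasible with an
#' explanatory note, except at exactly `(1, 1)` where the SS6 family takes
#' over.
#'
#' @param params An [dimensionless_params()] object.
#' @param M_star Numeric matrix level used to evaluate the Jacobian for the
#'   free-matrix states (default 1).
#' @param family_TA `T_A` value at which the SS6 one-parameter family is
#'   reported when `(c_MA, c_AM) = (1, 1)` (default 0.5).
#' @param include_trivial Also return the all-extinct state
#'   `(0, 0, 0, 0, M*)` (default `FALSE`).
#' @param zero_tol Threshold below which an eigenvalue real part counts as
#'   zero (default 1e-8).
#' @return A tibble with one row per state: `label`, the five components
#'   (`M` is `M_star` where free), `M_free`, `feasible`, `stability`,
#'   `leading_re`, `stability_non_ecm`, `leading_re_non_ecm`, `note`.
#' @examples
#' steady_states(dimensionless_params(c_MA = 0.5, c_AM = 0.5))
#' @export
steady_states <- function(params, M_star = 1, family_TA = 0.5,
                          include_trivial = FALSE, zero_tol = 1e-8) {
  stopifnot(inherits(params, "invasion_params"))
  cMA <- params$c_MA; cAM <- params$c_AM
  delta <- params$delta; cS <- params$c_S

  rows <- list()
  add <- function(label, S, T_A, T_M, L, M, M_free, note = NA_character_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      label = label, S = S, T_A = T_A, T_M = T_M, L = L,
      M = if (M_free) M_star else M, M_free = M_free, note = note)
  }

  if (include_trivial) add("trivial", 0, 0, 0, 0, NA_real_, TRUE)
  add("SS0", 1, 0, 0, 0, NA_real_, TRUE)
  add("SS1", 0, 1, 0, 1, NA_real_, TRUE)
  add("SS2", 0, 0, 1, 0, 0, FALSE)

  q <- 1 - cMA * cAM
  if (abs(q) < 1e-12) {
    add("SS3", NA_real_, NA_real_, NA_real_, NA_real_, 0, FALSE,
        note = "degenerate denominator: c_MA * c_AM = 1")
  } else {
    TA3 <- (1 - cMA) / q
    TM3 <- (1 - cAM) / q
    add("SS3", 0, TA3, TM3, TA3, 0, FALSE)
  }

  p4 <- 1 - cS * delta
  if (abs(p4) < 1e-12) {
    add("SS4", NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, TRUE,
        note = "degenerate denominator: c_S * delta = 1")
  } else {
    add("SS4", (1 - delta) / p4, (1 - cS) / p4, 0, (1 - cS) / p4,
        NA_real_, TRUE)
  }

  add("SS5", 1, 0, 1 - cS, 0, 0, FALSE)

  if (abs(cMA - 1) < 1e-12 && abs(cAM - 1) < 1e-12) {
    TA6 <- family_TA
    add("SS6", 1 - delta * TA6, TA6, 1 - cS - (1 - cS * delta) * TA6,
        TA6, 0, FALSE,
        note = sprintf("one-parameter family; reported at T_A = %g", TA6))
  } else {
    den <- 1 - cS * delta - cAM * cMA + cMA * cS * delta
    if (abs(den) < 1e-12) {
      add("SS6", NA_real_, NA_real_, NA_real_, NA_real_, 0, FALSE,
          note = "degenerate denominator")
    } else {
      TA6 <- (1 - cS - cMA + cMA * cS) / den
      TM6 <- (1 - cS - cAM + cAM * cS) / den
      S6 <- (1 - delta - cAM * cMA + cMA * delta) / den
      add("SS6", S6, TA6, TM6, TA6, 0, FALSE)
    }
  }

  out <- dplyr::bind_rows(rows)
  out$feasible <- is_feasible_state(out)

  cls <- purrr::pmap(out, function(label, S, T_A, T_M, L, M, M_free,
                                   note, feasible) {
    if (!feasible) {
      return(tibble::tibble(stability = "not-applicable",
                            leading_re = NA_real_,
                            stability_non_ecm = "not-applicable",
                            leading_re_non_ecm = NA_real_))
    }
    classify_stability(c(S = S, T_A = T_A, T_M = T_M, L = L, M = M),
                       params, zero_tol = zero_tol)
  })
  dplyr::bind_cols(out, dplyr::bind_rows(cls))[
    , c("label", "S", "T_A", "T_M", "L", "M", "M_free", "feasible",
        "stability", "leading_re", "stability_non_ecm",
        "leading_re_non_ecm", "note")]
}

# a state is feasible if all components are real and within [0,1]
# (populations cannot be negative; densities are scaled to at most 1)
is_feasible_state <- function(df) {
  comp <- as.matrix(df[, c("S", "T_A", "T_M", "L", "M")])
  apply(comp, 1, function(v) all(is.finite(v)) &&
          all(v >= -1e-12) && all(v <= 1 + 1e-12))
}

#' Linear stability of a homogeneous state
#'
#' Computes the eigenvalues of the analytic reaction Jacobian at the given
#' state and labels it `stable` (all real parts below `-zero_tol`),
#' `unstable` (any real part above `zero_tol`) or `marginal` (leading real
#' part within `zero_tol` of zero). The marginal case arises structurally
#' for matrix-retaining states: when `T_M = 0` the matrix row of the
#' Jacobian vanishes and contributes an exact zero eigenvalue, which is
#' detected structurally rather than numerically. The classification
#' restricted to the non-matrix subspace (dropping the `M` row and column)
#' is reported alongside.
#'
#' @param state Named vector or one-row data frame with `S, T_A, T_M, L, M`.
#' @param params An [dimensionless_params()] object.
#' @param zero_tol Eigenvalue zero threshold (default 1e-8).
#' @return A one-row tibble: `stability`, `leading_re`,
#'   `stability_non_ecm`, `leading_re_non_ecm`.
#' @export
classify_stability <- function(state, params, zero_tol = 1e-8) {
  J <- kinetics_jacobian(state, params)
  s <- as.list(state)
  structural_zero <- abs(s$T_M) < zero_tol  # M row vanishes identically
  ev <- eigen(J, only.values = TRUE)$values
  lead <- max(Re(ev))
  ev4 <- eigen(J[1:4, 1:4], only.values = TRUE)$values
  lead4 <- max(Re(ev4))
  lab <- function(l) {
    if (l > zero_tol) "unstable" else if (l >= -zero_tol) "marginal"
    else "stable"
  }
  stability <- lab(lead)
  if (structural_zero && stability == "stable") stability <- "marginal"
  tibble::tibble(stability = stability, leading_re = lead,
                 stability_non_ecm = lab(lead4), leading_re_non_ecm = lead4)
}

#' Invasion scenario implied by the competition coefficients
#'
#' The two inter-phenotype competition coefficients partition the parameter
#' plane into four open quadrants relative to the intra-species level 1:
#' * `stable_coexistence` (`c_MA < 1`, `c_AM < 1`): both phenotypes coexist
#'   (SS3 stable) and the tumour invades fastest;
#' * `exclusion_of_TA` (`c_MA > 1`, `c_AM < 1`): the matrix-degraders
#'   eliminate the acid-producers and invasion halts (encapsulation);
#' * `exclusion_of_TM` (`c_MA < 1`, `c_AM > 1`): the acid-producers
#'   dominate; invasion is transient;
#' * `bistable` (both > 1): the outcome depends on the initial conditions.
#' Values within `tol` of either threshold are labelled `boundary`.
#'
#' @param c_MA,c_AM Competition coefficients (vectorised).
#' @param tol Boundary tolerance (default 1e-6).
#' @return Character vector of regime labels.
#' @examples
#' classify_regime(c(0.5, 1.2, 0.7, 1.7), c(0.5, 0.7, 1.2, 1.7))
#' @export
classify_regime <- function(c_MA, c_AM, tol = 1e-6) {
  stopifnot(all(c_MA >= 0), all(c_AM >= 0))
  dplyr::case_when(
    abs(c_MA - 1) <= tol | abs(c_AM - 1) <= tol ~ "boundary",
    c_MA < 1 & c_AM < 1 ~ "stable_coexistence",
    c_MA > 1 & c_AM < 1 ~ "exclusion_of_TA",
    c_MA < 1 & c_AM > 1 ~ "exclusion_of_TM",
    TRUE ~ "bistable"
  )
}

#' Critical competition strength by bisection
#'
#' Locates the value of a competition coefficient at which a target steady
#' state (SS1 or SS3) changes linear stability, by bisecting the sign change
#' of the leading eigenvalue real part of the Jacobian restricted to the
#' non-matrix subspace (the structural matrix zero mode is excluded so that
#' the genuine stability exchange is visible).
#'
#' @param params An [dimensionless_params()] object (`delta > 1`, `c_S > 1`
#'   assumed; its `c_MA`/`c_AM` entries are overridden along the search
#'   path).
#' @param target `"SS3"` or `"SS1"`.
#' @param axis Which coefficient varies: `"c_AM"`, `"c_MA"`, or
#'   `"symmetric"` (both together).
#' @param other_value Value held by the non-varying coefficient (ignored for
#'   `"symmetric"`; default 0.5).
#' @param interval Search interval (default `c(0, 2)`).
#' @param tol Bisection tolerance on the coefficient (default 1e-6).
#' @return The threshold value, or `NA` (with a message) if the leading
#'   eigenvalue does not change sign on the interval.
#' @examples
#' critical_competition(dimensionless_params(), "SS3", "symmetric")
#' @export
critical_competition <- function(params, target = c("SS3", "SS1"),
                                 axis = c("symmetric", "c_AM", "c_MA"),
                                 other_value = 0.5, interval = c(0, 2),
                                 tol = 1e-6) {
  target <- match.arg(target)
  axis <- match.arg(axis)
  stopifnot(inherits(params, "invasion_params"))

  leading <- function(cc) {
    cMA <- switch(axis, symmetric = cc, c_MA = cc, c_AM = other_value)
    cAM <- switch(axis, symmetric = cc, c_AM = cc, c_MA = other_value)
    p <- params
    p$c_MA <- cMA; p$c_AM <- cAM
    st <- if (target == "SS1") {
      c(S = 0, T_A = 1, T_M = 0, L = 1, M = 1)
    } else {
      q <- 1 - cMA * cAM
      if (abs(q) < 1e-10) return(NA_real_)  # degenerate; nudged by caller
      TA <- (1 - cMA) / q
      TM <- (1 - cAM) / q
      c(S = 0, T_A = TA, T_M = TM, L = TA, M = 0)
    }
    J <- kinetics_jacobian(st, p)
    max(Re(eigen(J[1:4, 1:4], only.values = TRUE)$values))
  }

  # SS3 is undefined where c_MA * c_AM = 1; evaluate a whisker inside the
  # interval instead (well below the bisection tolerance)
  eval_guarded <- function(cc) {
    v <- leading(cc)
    if (is.na(v)) v <- leading(cc - 1e-7)
    if (is.na(v)) v <- leading(cc + 1e-7)
    v
  }

  lo <- interval[1]; hi <- interval[2]
  flo <- eval_guarded(lo); fhi <- eval_guarded(hi)
  if (is.na(flo) || is.na(fhi) || sign(flo) == sign(fhi)) {
    message("no sign change of the leading non-matrix eigenvalue on [",
            lo, ", ", hi, "]")
    return(NA_real_)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- eval_guarded(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Write a steady-state report
#'
#' One row per state: label, components, free-matrix marker, feasibility and
#' stability labels, leading eigenvalues.
#'
#' @param ss A tibble from [steady_states()].
#' @param path Output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_steady_state_report <- function(ss, path) {
  readr::write_tsv(ss, path)
  invisible(path)
}
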