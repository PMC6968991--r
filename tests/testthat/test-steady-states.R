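test_that("enumerated states match their closed forms", {
  p <- default_params(c_MA = 0.5, c_AM = 0.5)
  ss <- steady_states(p)
  row <- function(lbl) ss[ss$label == lbl, ]

  expect_equal(unname(unlist(row("SS1")[, c("S", "T_A", "T_M", "L")])),
               c(0, 1, 0, 1))
  expect_true(row("SS1")$M_free)
  expect_equal(unname(unlist(row("SS2")[, c("S", "T_A", "T_M", "L", "M")])),
               c(0, 0, 1, 0, 0))
  expect_equal(unname(unlist(row("SS3")[, c("S", "T_A", "T_M", "L", "M")])),
               c(0, 2 / 3, 2 / 3, 2 / 3, 0))
  expect_equal(row("SS4")$S, (1 - 12.5) / (1 - 18.75))
  expect_equal(row("SS4")$T_A, (1 - 1.5) / (1 - 18.75))
  expect_equal(row("SS4")$S, 0.647887, tolerance = 1e-6)
  expect_equal(row("SS4")$T_A, 0.028169, tolerance = 1e-4)
  # matrix-degraders cannot coexist with dominant stroma
  expect_equal(row("SS5")$T_M, -0.5)
  expect_false(row("SS5")$feasible)
  expect_equal(row("SS5")$stability, "not-applicable")
})

test_that("asymmetric competition gives an asymmetric coexistence state", {
  p <- default_params(c_MA = 0.2, c_AM = 0.8)
  ss3 <- steady_states(p)
  ss3 <- ss3[ss3$label == "SS3", ]
  q <- 1 - 0.2 * 0.8
  expect_equal(ss3$T_A, (1 - 0.2) / q)
  expect_equal(ss3$T_M, (1 - 0.8) / q)
  expect_equal(ss3$L, ss3$T_A)
})

test_that("degenerate competition products are flagged", {
  p <- default_params(c_MA = 2, c_AM = 0.5)
  ss <- steady_states(p)
  s3 <- ss[ss$label == "SS3", ]
  expect_false(s3$feasible)
  expect_match(s3$note, "degenerate")

  # at exactly (1,1) the three-population family appears and satisfies the
  # kinetics at several points along the family
  p11 <- default_params(c_MA = 1, c_AM = 1)
  for (ta in c(0.02, 0.04, 0.07)) {
    ss6 <- steady_states(p11, family_TA = ta)
    s6 <- ss6[ss6$label == "SS6", ]
    res <- unlist(reaction_terms(s6[, c("S", "T_A", "T_M", "L", "M")], p11))
    expect_lt(max(abs(res)), 1e-12)
  }
})

test_that("stability classification reproduces the analytic conditions", {
  p <- default_params(c_MA = 0.5, c_AM = 0.5)
  ss <- steady_states(p)
  get <- function(lbl, col) ss[ss$label == lbl, ][[col]]

  expect_equal(get("SS3", "stability"), "stable")
  # matrix-retaining states carry the structural zero mode
  expect_equal(get("SS0", "stability"), "marginal")
  expect_equal(get("SS0", "stability_non_ecm"), "stable")
  expect_equal(get("SS4", "stability"), "unstable")

  # acid-producer monoculture stabilises once it suppresses the degraders
  p2 <- default_params(c_MA = 0.5, c_AM = 1.2)
  ss2 <- steady_states(p2)
  s1 <- ss2[ss2$label == "SS1", ]
  expect_equal(s1$stability, "marginal")
  expect_equal(s1$stability_non_ecm, "stable")

  # the degrader monoculture is unstable across the competition plane
  for (cs in list(c(0.3, 0.3), c(1.5, 0.5), c(0.5, 1.5), c(2, 2))) {
    pk <- default_params(c_MA = cs[1], c_AM = cs[2])
    ssk <- steady_states(pk)
    expect_equal(ssk[ssk$label == "SS2", ]$stability, "unstable")
  }
})

test_that("regime classification covers the four quadrants and the
          boundary", {
  expect_equal(classify_regime(1.2, 0.7), "exclusion_of_TA")
  expect_equal(classify_regime(0.7, 1.2), "exclusion_of_TM")
  expect_equal(classify_regime(1.7, 1.7), "bistable")
  expect_equal(classify_regime(0.2, 0.9), "stable_coexistence")
  expect_equal(classify_regime(1, 0.4), "boundary")
  expect_equal(classify_regime(c(0.5, 1.5), c(0.5, 1 + 1e-9)),
               c("stable_coexistence", "boundary"))
})

test_that("regime labels agree with the stability of SS1 and SS3 inside the
          open quadrants", {
  for (cs in list(c(0.5, 0.5), c(1.5, 0.5), c(0.5, 1.5), c(1.5, 1.5))) {
    p <- default_params(c_MA = cs[1], c_AM = cs[2])
    regime <- classify_regime(cs[1], cs[2])
    ss <- steady_states(p)
    s3 <- ss[ss$label == "SS3", ]
    s1 <- ss[ss$label == "SS1", ]
    if (regime == "stable_coexistence") {
      expect_equal(s3$stability, "stable")
      expect_equal(s1$stability_non_ecm, "unstable")
    }
    if (regime == "exclusion_of_TM") {
      expect_equal(s1$stability_non_ecm, "stable")
    }
    if (regime == "exclusion_of_TA") {
      expect_equal(s1$stability_non_ecm, "unstable")
      expect_true(!s3$feasible || s3$stability == "unstable")
    }
    if (regime == "bistable") {
      # both monoculture-side states attract; coexistence is a saddle
      expect_equal(s1$stability_non_ecm, "stable")
      expect_true(s3$feasible && s3$stability == "unstable")
    }
  }
})

test_that("bisection locates the stability exchange of SS3 and SS1 at unit
          competition", {
  p <- default_params()
  expect_equal(critical_competition(p, "SS3", "symmetric"), 1,
               tolerance = 2e-6)
  expect_equal(critical_competition(p, "SS3", "c_AM", other_value = 0.5), 1,
               tolerance = 2e-6)
  # along the c_MA axis the stroma-reinvasion mode crosses first: the S
  # eigenvalue at SS3 is 1 - delta * T_A*, which hits zero where
  # (1 - c)/(1 - c/2) = 1/delta, i.e. at c = (delta - 1)/(delta - 1/2),
  # slightly before the competition mode at c = 1
  expect_equal(critical_competition(p, "SS3", "c_MA", other_value = 0.5),
               (12.5 - 1) / (12.5 - 0.5), tolerance = 2e-6)
  expect_equal(critical_competition(p, "SS1", "c_AM"), 1, tolerance = 2e-6)
  # no exchange along a path where the state never stabilises
  expect_message(
    res <- critical_competition(p, "SS1", "c_MA", other_value = 0.5),
    "no sign change")
  expect_true(is.na(res))
})

test_that("a dense multi-start root search finds no feasible equilibrium
          missing from the enumeration", {
  set.seed(99)
  n_missing <- 0
  for (draw in 1:10) {
    p <- default_params(delta = runif(1, 8, 16), rho_L = runif(1, 50, 90),
                        kappa = runif(1, 5, 15), c_S = runif(1, 1.2, 1.8),
                        c_MA = runif(1, 0, 2), c_AM = runif(1, 0, 2))
    if (abs(p$c_MA * p$c_AM - 1) < 0.05) next
    known <- steady_states(p, include_trivial = TRUE)
    known <- known[known$feasible, c("S", "T_A", "T_M", "L", "M")]
    starts <- matrix(runif(5 * 100, 0, 1.2), ncol = 5)
    for (i in seq_len(nrow(starts))) {
      root <- newton_equilibrium(starts[i, ], p)
      if (is.null(root)) next
      # feasibility filter: within the physical box
      if (any(root < -1e-9) || any(root > 1.2)) next
      # match against the enumeration; matrix-free states match on the
      # first four components only (any matrix level is admissible)
      matched <- FALSE
      for (k in seq_len(nrow(known))) {
        ref <- unlist(known[k, ])
        if (abs(root[3]) < 1e-8 && abs(ref[3]) < 1e-8) {
          if (max(abs(root[1:4] - ref[1:4])) < 1e-6) matched <- TRUE
        } else if (max(abs(root - ref)) < 1e-6) {
          matched <- TRUE
        }
        if (matched) break
      }
      if (!matched) n_missing <- n_missing + 1
    }
  }
  expect_equal(n_missing, 0)
})
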