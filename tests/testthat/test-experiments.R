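# experiment-driver behaviour at reduced problem sizes (coarser grids and
# shorter horizons keep each block inside a few seconds; the full-scale runs
# live in the acceptance suite)

test_that("single-population runs gate the other phenotype and leave the
          matrix untouched without degraders", {
  g <- grid_1d(100)
  r <- run_single_population("T_A", t_end = 20, grid = g,
                             settings = fast_settings(),
                             times = c(0, 10, 20))
  s0 <- snapshot_at(r$sim, 0)
  s20 <- snapshot_at(r$sim, 20)
  expect_equal(max(abs(s20$T_M)), 0)
  # no degraders anywhere: the matrix field is time-invariant
  expect_equal(s20$M, s0$M, tolerance = 1e-7)
  expect_equal(nrow(r$front_series), 3)
  expect_s3_class(glance(r), "tbl_df")
})

test_that("a run with no population present is rejected", {
  expect_error(
    run_single_population("both"), "arg")
})

test_that("competition sweep records every combination with populated
          metrics and survives individual failures", {
  g <- grid_1d(60)
  sw <- run_competition_sweep(c_MA = c(0, 1, 2), c_AM = c(0, 1, 2),
                              t_end = 4, grid = g,
                              settings = fast_settings())
  expect_equal(nrow(sw), 9)
  expect_true(all(!is.na(sw$front_either)))
  expect_true(all(!is.na(sw$mass)))
  expect_true(all(sw$mass >= 0))
  expect_true(all(is.na(sw$error)))
  expect_setequal(unique(sw$regime),
                  c("stable_coexistence", "boundary", "exclusion_of_TA",
                    "exclusion_of_TM", "bistable"))
  # fronts stay inside the domain
  expect_true(all(sw$front_either >= 0 & sw$front_either <= 1))
})

test_that("sweep results are reproducible record by record", {
  g <- grid_1d(60)
  one <- run_competition_sweep(c_MA = 0.4, c_AM = 1.3, t_end = 6, grid = g,
                               settings = fast_settings())
  two <- run_competition_sweep(c_MA = 0.4, c_AM = 1.3, t_end = 6, grid = g,
                               settings = fast_settings())
  expect_equal(one$front_either, two$front_either)
  expect_equal(one$mass, two$mass)
})

test_that("snapshot experiment labels the coexistence outcome and returns
          fronts", {
  e <- run_snapshot_experiment(0, 0, grid = grid_1d(100),
                               settings = fast_settings(),
                               times = c(0, 10, 20, 25))
  expect_equal(e$outcome, "mixed_invasion")
  expect_false(e$extinct_TA)
  expect_false(e$extinct_TM)
  expect_gt(e$fronts$front[4], e$fronts$front[1] + 0.05)
})

test_that("null perturbation reproduces the unperturbed run; a spatial
          offset separates the phenotypes", {
  g <- grid_1d(100)
  null <- run_perturbation_experiment(amplitude = 0, grid = g,
                                      settings = fast_settings(),
                                      times = c(0, 10, 20, 25))
  expect_lt(max(abs(as.matrix(null$perturbed[, -(1:2)]) -
                      as.matrix(null$unperturbed[, -(1:2)]))), 1e-7)
  expect_false(null$summary$separated)

  off <- run_perturbation_experiment(mode = "spatial-offset", grid = g,
                                     settings = fast_settings(),
                                     times = c(0, 10, 20, 25))
  expect_true(off$summary$separated)
  expect_lt(off$summary$mixing_perturbed, 0.2)
  expect_gt(off$summary$mixing_unperturbed, 0.8)
})

test_that("with no matrix degradation the matrix is frozen and the front
          stalls at the wall", {
  g <- grid_1d(100)
  p <- default_params(kappa = 0)
  sim <- simulate_invasion(params = p, grid = g, times = c(0, 10, 25),
                           settings = fast_settings())
  s0 <- snapshot_at(sim, 0)
  s25 <- snapshot_at(sim, 25)
  expect_equal(s25$M, s0$M, tolerance = 1e-7)
  expect_lt(front_position(s25, "either"), 0.32)
})

test_that("kappa sensitivity produces one aligned table per rate and a
          kappa-dependent asymmetry", {
  ks <- run_kappa_sensitivity(kappa_values = c(5, 10),
                              c_values = c(0.3, 0.7),
                              t_end = 50, grid = grid_1d(100),
                              settings = fast_settings())
  expect_length(ks$sweeps, 2)
  expect_equal(nrow(ks$sweeps[[1]]), 4)
  expect_equal(ks$sweeps[[1]][, c("c_MA", "c_AM")],
               ks$sweeps[[2]][, c("c_MA", "c_AM")])
  a <- tidy(ks)
  expect_equal(names(a), c("kappa", "asymmetry"))
  # the invaded distance favours the degrader-suppressed orientation, and
  # the imbalance genuinely responds to the degradation rate
  expect_true(all(a$asymmetry < 0))
  expect_gt(abs(a$asymmetry[1] - a$asymmetry[2]), 2e-3)
})

test_that("tidy and autoplot interfaces produce well-formed output", {
  g <- grid_1d(60)
  sim <- simulate_invasion(params = default_params(), grid = g,
                           times = c(0, 5), settings = fast_settings())
  long <- tidy(sim)
  expect_equal(nrow(long), 2 * 60 * 5)
  expect_s3_class(glance(sim), "tbl_df")
  expect_s3_class(autoplot(sim), "ggplot")
  sw <- run_competition_sweep(c_MA = c(0, 2), c_AM = c(0, 2), t_end = 2,
                              grid = g, settings = fast_settings())
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(autoplot(sw, metric = "mass"), "ggplot")
  expect_s3_class(plot_regime_map(seq(0, 2, 0.5)), "ggplot")
})
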