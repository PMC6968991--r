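test_that("pointwise stencil reproduces textbook cases", {
  # unit spike with unit mobility: the standard three-point Laplacian
  expect_equal(diffusion_stencil(c(0, 1, 0), c(1, 1, 1), h = 1, r = 2), -2)
  # zero mobility blocks all flux
  expect_equal(diffusion_stencil(c(0, 1, 0), c(0, 0, 0), h = 1, r = 2), 0)
  # a linear profile has zero second difference under constant mobility
  expect_equal(diffusion_stencil(c(0, 1, 2), c(3, 3, 3), h = 1, r = 2), 0)
  expect_error(diffusion_stencil(c(0, 1, 0), c(1, 1, 1), h = 1, r = 1),
               "interior")
})

test_that("full-grid stencil equals an independently built tridiagonal
          operator", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:20, 1)
    u <- runif(n)
    D <- runif(n)
    h <- 1 / (n - 1)
    got <- diffusion_stencil(u, D, h)
    A <- stencil_operator_matrix(D, h)
    expect_equal(got[2:(n - 1)], as.numeric(A %*% u)[2:(n - 1)])
    # boundary rows follow by reflecting u and D through the boundary
    ue <- c(u[2], u, u[n - 1])
    De <- c(D[2], D, D[n - 1])
    Ae <- stencil_operator_matrix(De, h)
    expect_equal(got[c(1, n)], as.numeric(Ae %*% ue)[c(2, n + 1)])
  }
})

test_that("assemble_rhs equals the pure kinetics for uniform states and
          vanishes at the healthy state", {
  p <- default_params(c_MA = 0.4, c_AM = 1.1)
  g <- grid_1d(40)
  uni <- tibble::tibble(x = g$x, S = 0.6, T_A = 0.3, T_M = 0.2, L = 0.25,
                        M = 0.7)
  d <- assemble_rhs(uni, p, g)
  r <- reaction_terms(uni, p)
  expect_equal(as.matrix(d), as.matrix(r))

  ss0 <- tibble::tibble(x = g$x, S = 1, T_A = 0, T_M = 0, L = 0, M = 0.42)
  expect_equal(max(abs(as.matrix(assemble_rhs(ss0, p, g)))), 0)
})

test_that("the pure diffusion operator conserves trapezoidal mass under
          zero-flux boundaries", {
  g <- grid_1d(101)
  spike <- rep(0, g$n_points)
  spike[47] <- 1
  st <- tibble::tibble(x = g$x, S = 0, T_A = 0, T_M = 0, L = spike, M = 0.5)
  d <- assemble_rhs(st, default_params(), g, reaction = FALSE)
  expect_lt(abs(pracma::trapz(g$x, d$dL)), 1e-12)
})

test_that("negativity guard is inactive on non-negative states and linear
          below zero", {
  st <- random_state(30, seed = 3)
  z <- negativity_guard(st, rate = 100)
  expect_equal(max(abs(as.matrix(z))), 0)
  st$L[10] <- -1e-8
  z2 <- negativity_guard(st, rate = 100)
  expect_equal(z2$dL[10], 1e-6)
  expect_equal(sum(as.matrix(z2) != 0), 1)
})

test_that("uniform logistic stroma follows the closed-form solution", {
  g <- grid_1d(50)
  st <- tibble::tibble(x = g$x, S = 0.5, T_A = 0, T_M = 0, L = 0, M = 0)
  sim <- simulate_invasion(init = st, params = default_params(), grid = g,
                           times = c(0, log(3)), settings = fast_settings())
  fin <- snapshot_at(sim, log(3))
  # S0 e^t / (1 + S0 (e^t - 1)) with S0 = 1/2, t = ln 3 gives 3/4
  expect_equal(fin$S, rep(0.75, 50), tolerance = 1e-6)
  expect_equal(max(abs(fin$T_A)), 0)
})

test_that("equilibrium initial data are preserved", {
  g <- grid_1d(40)
  ss0 <- tibble::tibble(x = g$x, S = 1, T_A = 0, T_M = 0, L = 0, M = 1)
  sim <- simulate_invasion(init = ss0, params = default_params(), grid = g,
                           times = c(0, 10, 30), settings = fast_settings())
  fin <- snapshot_at(sim, 30)
  expect_equal(as.matrix(fin[, -1]), as.matrix(ss0[, -1]), tolerance = 1e-7)
})

test_that("spatial error of the transport scheme decreases at second
          order", {
  # heat equation for the acid field alone: L(x,t) = 1 + cos(pi x) e^(-pi^2 t)
  p <- default_params(rho_L = 0)
  t_end <- 0.02
  err <- vapply(c(26, 51, 101), function(n) {
    g <- grid_1d(n)
    st <- tibble::tibble(x = g$x, S = 0, T_A = 0, T_M = 0,
                         L = 1 + cos(pi * g$x), M = 0)
    sim <- simulate_invasion(init = st, params = p, grid = g,
                             times = c(0, t_end),
                             settings = solver_settings(1e-11, 1e-11))
    exact <- 1 + cos(pi * g$x) * exp(-pi^2 * t_end)
    max(abs(snapshot_at(sim, t_end)$L - exact))
  }, numeric(1))
  orders <- log2(err[-3] / err[-1])
  expect_true(all(orders > 1.7 & orders < 2.3))
})

test_that("integration is deterministic and matches the pure-R right-hand
          side", {
  g <- grid_1d(60)
  p <- default_params(c_MA = 0.7, c_AM = 1.2)
  s1 <- simulate_invasion(params = p, grid = g, times = c(0, 2),
                          settings = fast_settings())
  s2 <- simulate_invasion(params = p, grid = g, times = c(0, 2),
                          settings = fast_settings())
  expect_identical(as.matrix(s1[, -1]), as.matrix(s2[, -1]))

  sR <- simulate_invasion(params = p, grid = g, times = c(0, 2),
                          settings = fast_settings(use_compiled = FALSE))
  expect_lt(max(abs(as.matrix(s1[, -1]) - as.matrix(sR[, -1]))), 1e-6)
})

test_that("matrix density never increases along a trajectory and fields stay
          essentially non-negative", {
  g <- grid_1d(100)
  sim <- simulate_invasion(params = default_params(), grid = g,
                           times = c(0, 5, 15, 30),
                           settings = fast_settings())
  tt <- unique(sim$time)
  prev <- snapshot_at(sim, tt[1])$M
  for (k in 2:length(tt)) {
    cur <- snapshot_at(sim, tt[k])$M
    expect_true(all(cur <= prev + 1e-7))
    prev <- cur
  }
  expect_gt(min(as.matrix(sim[, c("S", "T_A", "T_M", "L", "M")])), -1e-7)
})

test_that("invalid snapshot schedules are rejected", {
  expect_error(simulate_invasion(times = c(0, 2, 2)), "strictly increasing")
  expect_error(simulate_invasion(times = c(-1, 2)), "strictly increasing")
})
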