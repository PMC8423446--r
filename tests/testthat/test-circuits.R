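test_that("geometry defaults reproduce the canonical arrangements", {
  g <- regulator_geometry(2, 1)
  expect_equal(g$sigma, matrix(c(1, -1), ncol = 1))
  g4 <- regulator_geometry(4, 2)
  expect_equal(g4$angles, c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(g4$sigma[3, ], -g4$sigma[1, ]) # two +/- pairs
  g1 <- regulator_geometry(1, 2, angles = pi / 4)
  expect_equal(g1$sigma, cbind(cos(pi / 4), sin(pi / 4)))
  # SEPI arrangement for Na = Nx = 2
  expect_equal(regulator_geometry(2, 2)$angles, c(0, pi / 2))
  # rows are unit length for any explicit sigma
  ge <- suppressWarnings(regulator_geometry(3, 2, sigma = matrix(rnorm(6), 3)))
  expect_equal(rowSums(ge$sigma^2), rep(1, 3))
  expect_error(regulator_geometry(2, 3), "sigma")
  # a single regulator pointing away from the mean cannot mean-match
  expect_warning(regulator_geometry(1, 2, angles = 3 * pi / 4),
                 "positively span")
  expect_warning(regulator_geometry(2, 1, sigma = matrix(c(-1, -1), 2)),
                 "positively span")
})

test_that("SEPI adapts to any static demand (x -> 1, P -> D)", {
  # fixed point: start there, stay there
  dem1 <- static_demand(1, duration = 50)
  s1 <- simulate_sepi(dem1, learning_params(a0 = 1))
  expect_true(all(s1$x == 1))
  expect_true(all(s1$P == 1))
  # convergence from arbitrary positive start
  dem2 <- static_demand(2, duration = 400)
  s2 <- simulate_sepi(dem2, learning_params(a0 = 0.5))
  n <- nrow(s2$P)
  expect_lt(abs(s2$x[n, 1] - 1), 1e-4)
  expect_lt(abs(s2$P[n, 1] - 2), 2e-4)
})

test_that("learning circuit is stationary at mean-matching states (kappa=0)", {
  dem <- static_demand(1, duration = 20)
  geom <- regulator_geometry(2, 1)
  pars <- learning_params(kappa = 0, a0 = c(1.7, 0.7)) # sigma^T a = 1
  circ <- simulate_learning(dem, geom, pars)
  expect_true(all(circ$a[, 1] == 1.7))
  expect_true(all(circ$a[, 2] == 0.7))
  expect_true(all(circ$x == 1))
})

test_that("learning circuit adapts to static demand with O(kappa) offset", {
  dem <- static_demand(1, duration = 1500)
  for (kap in c(1e-3, 1e-2)) {
    circ <- simulate_learning(dem, regulator_geometry(2, 1),
                              learning_params(kappa = kap), discard = 0.5)
    xbar <- circ$epoch_stats$performance # placeholder to silence lint
    xoff <- abs(mean(circ$x[round(0.8 * nrow(circ$x)):nrow(circ$x), 1]) - 1)
    expect_gt(xoff, kap / 10)
    expect_lt(xoff, 3 * kap)
  }
})

test_that("1D learning pair encodes the mean and self-tunes reactivity", {
  sched <- variance_schedule(c(0.02, 0.06), duration = 1500, dt = 1e-3)
  dem <- simulate_demand(sched, seed = 4)
  circ <- simulate_learning(dem, regulator_geometry(2, 1), discard = 0.4,
                            record_every = 16L)
  a_diff <- circ$mean_a[, 1] - circ$mean_a[, 2]
  a_sum <- circ$mean_a[, 1] + circ$mean_a[, 2]
  expect_lt(max(abs(a_diff - 1)), 0.05)   # a+ - a- ~ mean demand
  expect_gt(a_sum[2], a_sum[1])           # reactivity grows with Gamma
  # activities never fall below the floor under self-activation
  expect_true(all(circ$a >= circ$params$a_floor))
  # SEPI on the same demand: single-regulator activity essentially unchanged
  sep <- simulate_sepi(dem, discard = 0.4, record_every = 16L)
  expect_lt(abs(diff(sep$mean_a[, 1])), 0.05)
  expect_gt(circ$epoch_stats$performance[2],
            sep$epoch_stats$performance[2])
})

test_that("without self-activation and with d = -10 the circuit is SEPI-like", {
  dem <- simulate_demand(env2d(0.05, dt = 1e-3), seed = 6, duration = 1500)
  lin <- simulate_learning(dem, regulator_geometry(2, 2),
                           learning_params(kappa = 1e-4, d = -10,
                                           self_activation = FALSE),
                           discard = 0.5, record_every = 64L)
  sep <- simulate_sepi(dem, discard = 0.5, record_every = 64L)
  expect_lt(abs(lin$epoch_stats$performance[1] /
                  sep$epoch_stats$performance[1] - 1), 0.05)
})

test_that("analytic responsiveness matches its closed forms", {
  geom <- regulator_geometry(2, 1)
  pars <- learning_params()
  expect_equal(responsiveness_analytic(c(0, 0), geom, pars),
               matrix(0, 1, 1))
  R <- responsiveness_analytic(c(2.5, 1.5), geom, pars)
  expect_equal(R[1, 1], (2.5 + 1.5) / pars$tau_a)
  # PSD and symmetric in 2D
  g5 <- regulator_geometry(5, 2)
  a <- runif(5, 0, 3)
  R2 <- responsiveness_analytic(a, g5, pars)
  expect_equal(R2, t(R2))
  expect_true(all(eigen(R2, symmetric = TRUE)$values >= -1e-12))
})

test_that("finite-difference responsiveness matches analytic within 1%", {
  set.seed(42)
  pars <- learning_params(d = -1) # all regulators on the linear branch
  for (rep in 1:20) {
    na <- sample(3:6, 1)
    geom <- regulator_geometry(na, 2,
                               angles = runif(1, 0, 2 * pi) +
                                 2 * pi * (seq_len(na) - 1) / na)
    # activities that mean-match exactly (P = (1,1)): the minimum-norm
    # solution plus a positive shift along the null space (sum sigma_mu = 0)
    a <- as.vector(geom$sigma %*% solve(crossprod(geom$sigma), c(1, 1)))
    a <- a - min(a) + runif(1, 0.2, 2)
    D <- c(1, 1) * (1 + runif(2, -1e-3, 1e-3)) # near, not at, the set point
    est <- responsiveness_empirical(a, D, geom, pars)
    ana <- responsiveness_analytic(a, geom, pars)
    expect_false(any(est$kink))
    expect_lt(max(abs(est$R - ana)), 0.01 * max(abs(ana)))
  }
})

test_that("rectifier kink is detected and handled one-sidedly", {
  geom <- regulator_geometry(2, 1)
  pars <- learning_params(d = 0)
  a <- c(2, 1)
  est <- responsiveness_empirical(a, sum(geom$sigma * a), geom, pars)
  expect_true(est$kink[1])
  expect_true(is.finite(est$R[1, 1]))
})
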