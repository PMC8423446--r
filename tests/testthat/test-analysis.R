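test_that("performance is zero for perfect tracking and never positive", {
  dem <- static_demand(1, duration = 30)
  circ <- simulate_sepi(dem, learning_params(a0 = 1))
  expect_identical(performance(circ, dem), 0)
  dem2 <- simulate_demand(ou_params(gamma = 0.05, dt = 0.01), seed = 31,
                          duration = 200)
  circ2 <- simulate_sepi(dem2)
  expect_lt(performance(circ2, dem2), 0)
})

test_that("frozen production scores the stationary demand variance", {
  env <- ou_params(gamma = 0.05, dt = 0.01)
  perfs <- vapply(1:4, function(s) {
    dem <- simulate_demand(env, seed = 40 + s, duration = 5000)
    simulate_policy(optimal_policy(env, Inf), dem)$performance
  }, 1)
  expect_lt(abs(mean(perfs) - (-0.05)), 3 * sd(perfs) / 2)
})

test_that("R-level performance matches the simulator's epoch summaries", {
  sched <- variance_schedule(c(0.02, 0.08), duration = 200, dt = 1e-3)
  dem <- simulate_demand(sched, seed = 17)
  circ <- simulate_learning(dem, regulator_geometry(2, 1), discard = 0.3)
  expect_equal(performance(circ, dem, discard = 0.3),
               circ$epoch_stats$performance, tolerance = 1e-12)
  expect_equal(control_input_power(circ, dem, discard = 0.3),
               circ$epoch_stats$cip, tolerance = 1e-9)
  rep <- performance_report(circ, dem, discard = 0.3)
  expect_s3_class(rep, "performance_report")
  expect_equal(rep$performance, circ$epoch_stats$performance,
               tolerance = 1e-12)
  expect_identical(attr(rep, "seed"), 17L)
})

test_that("misaligned grids are rejected", {
  dem <- simulate_demand(ou_params(gamma = 0.02, dt = 0.01), seed = 1,
                         duration = 50)
  other <- simulate_demand(ou_params(gamma = 0.02, dt = 0.02), seed = 1,
                           duration = 50)
  circ <- simulate_sepi(dem)
  expect_error(performance(circ, other), "misaligned")
})

test_that("learned angle extracts the dominant eigenvector modulo pi", {
  expect_true(is.na(learned_angle(diag(2))))
  expect_true(attr(learned_angle(diag(2)), "undefined"))
  for (th in c(0.1, 1.2, 2.8, pi - 0.01)) {
    v <- c(cos(th), sin(th))
    expect_equal(learned_angle(outer(v, v)), th %% pi, tolerance = 1e-10)
  }
  expect_warning(ang <- learned_angle(matrix(c(1, 0.3, 0, 2), 2)),
                 "symmetric")
  expect_false(is.na(ang))
})

test_that("SEPI responsiveness is fixed while the learning pair's grows", {
  # SEPI: a linear single-activator circuit; at its operating point a ~ dbar
  # the responsiveness is 1/tau_a regardless of fluctuation strength
  sepi_geom <- regulator_geometry(1, 1)
  sepi_pars <- learning_params(kappa = 0, d = -1e6, self_activation = FALSE)
  R <- responsiveness_empirical(1, 1, sepi_geom, sepi_pars)
  expect_equal(R$R[1, 1], 1 / sepi_pars$tau_a, tolerance = 1e-6)
  expect_equal(responsiveness_analytic(1, sepi_geom, sepi_pars)[1, 1],
               1 / sepi_pars$tau_a)
  expect_equal(responsiveness_empirical(numeric(2) * 0, c(1, 1),
                                        regulator_geometry(2, 2),
                                        learning_params(d = -1))$R,
               matrix(0, 2, 2), tolerance = 1e-9)
})

test_that("gamma threshold rises with degradation and geometry alignment", {
  geom <- regulator_geometry(5, 2)
  env <- env2d(0.01, dt = 5e-3)
  g1 <- gamma_threshold(geom, env_template = env, kappa = 1e-3,
                        duration = 1000, iters = 9, seed = 3)
  g2 <- gamma_threshold(geom, env_template = env, kappa = 1e-2,
                        duration = 1000, iters = 9, seed = 3)
  g0 <- gamma_threshold(geom, env_template = env, kappa = 0,
                        duration = 1000, iters = 9, seed = 3)
  expect_lt(g1, g2)
  expect_lte(g0, g1)
  # a regulator aligned with the dominant fluctuation direction engages
  # learning at weaker fluctuations than a maximally misaligned arrangement
  # (five regulators cover directions modulo pi every 36 degrees, so the
  # rotated variant puts the nearest regulator 18 degrees off-axis)
  aligned <- regulator_geometry(5, 2, angles = pi / 4 + 2 * pi * (0:4) / 5)
  misaligned <- regulator_geometry(5, 2,
                                   angles = pi / 4 + pi / 10 +
                                     2 * pi * (0:4) / 5)
  ga <- gamma_threshold(aligned, env_template = env, kappa = 0.02,
                        duration = 1000, iters = 9, seed = 3)
  gm <- gamma_threshold(misaligned, env_template = env, kappa = 0.02,
                        duration = 1000, iters = 9, seed = 3)
  expect_lt(ga, gm)
})

test_that("sweep drivers return tidy, reproducible grids", {
  df <- sweep_gamma(c(0.02, 0.08), duration = 300, seeds = 1,
                    specs = list(circuit_spec("sepi")))
  expect_equal(names(df), c("gamma", "circuit", "seed", "performance",
                            "cip"))
  expect_equal(nrow(df), 2)
  df2 <- sweep_gamma(c(0.02, 0.08), duration = 300, seeds = 1,
                     specs = list(circuit_spec("sepi")))
  expect_identical(df, df2)
  expect_error(run_sweep(list(type = "nope")), "sweep spec")
  df3 <- run_sweep(list(type = "gamma", gammas = 0.02, duration = 300,
                        seeds = 1, specs = list(circuit_spec("sepi"))))
  expect_equal(df3$performance, df$performance[df$gamma == 0.02])
})
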