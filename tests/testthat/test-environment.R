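test_that("anisotropy matrix has the prescribed rotation and spectrum", {
  expect_equal(anisotropy_matrix(0, 10, 1), diag(c(1, 10)))
  expect_equal(anisotropy_matrix(pi / 4, 10, 1),
               matrix(c(5.5, -4.5, -4.5, 5.5), 2, 2))
  for (al in c(0.3, 1.1, 2.9)) {
    M <- anisotropy_matrix(al, 10, 1)
    ev <- eigen(M, symmetric = TRUE)
    expect_equal(sort(ev$values), c(1, 10))
    expect_equal(max(ev$values) / min(ev$values), 10)
    # low-stiffness eigenvector points along alpha
    v <- ev$vectors[, 2]
    expect_lt(abs(((atan2(v[2], v[1]) - al + pi / 2) %% pi) - pi / 2), 1e-10)
  }
  expect_error(anisotropy_matrix(0, 1, -1), "lambda")
  expect_error(anisotropy_matrix(0, 1, 2), "lambda")
})

test_that("stationary statistics follow gamma * M^-1", {
  s <- stationary_stats(ou_params(dbar = 1, M = 2, gamma = 0.1))
  expect_equal(s$covariance[1, 1], 0.05)
  # isotropic M: no preferred direction
  s2 <- stationary_stats(ou_params(dbar = c(1, 1), M = 3 * diag(2),
                                   gamma = 0.3))
  expect_equal(s2$covariance, 0.1 * diag(2))
  # eigenvectors shared with M
  M <- anisotropy_matrix(pi / 3)
  s3 <- stationary_stats(ou_params(dbar = c(1, 1), M = M, gamma = 0.05,
                                   dt = 5e-3))
  expect_equal(s3$covariance %*% M, M %*% s3$covariance, tolerance = 1e-10)
})

test_that("ou_params validates its invariants", {
  expect_error(ou_params(M = matrix(c(1, 2, 0, 1), 2),
                         dbar = c(1, 1)), "symmetric")
  expect_error(ou_params(M = -1), "positive definite")
  expect_error(ou_params(gamma = -1), "gamma")
  expect_error(ou_params(M = 20, dt = 0.01), "dt")
})

test_that("zero noise keeps the demand at its mean exactly", {
  dem <- simulate_demand(ou_params(gamma = 0, dt = 0.01), seed = 7,
                         duration = 20)
  expect_true(all(dem$D == 1))
  expect_identical(dem$clamp_count, 0)
})

test_that("identical seeds give bit-identical trajectories", {
  sched <- variance_schedule(c(0.02, 0.05), duration = 30, dt = 0.01)
  d1 <- simulate_demand(sched, seed = 11)
  d2 <- simulate_demand(sched, seed = 11)
  d3 <- simulate_demand(sched, seed = 12)
  expect_identical(d1$D, d2$D)
  expect_false(identical(d1$D, d3$D))
})

test_that("empirical stationary variance matches gamma / M (1D)", {
  dem <- simulate_demand(ou_params(gamma = 0.05, dt = 0.01), seed = 3,
                         duration = 5e4)
  v <- var(dem$D[, 1])
  # effective sample size T / (2 tau) with tau = 1/M
  se <- 0.05 * sqrt(2 / (5e4 / 2))
  expect_lt(abs(v - 0.05), 3 * se)
  expect_lt(abs(mean(dem$D[, 1]) - 1), 3 * sqrt(0.05 / (5e4 / 2)))
})

test_that("empirical 2D covariance has the prescribed eigenstructure", {
  al <- pi / 4
  dem <- simulate_demand(env2d(0.05, al, dt = 5e-3), seed = 5,
                         duration = 2e4)
  S <- cov(dem$D)
  eg <- eigen(S, symmetric = TRUE)
  # principal axis within 5 degrees of alpha
  v <- eg$vectors[, 1]
  expect_lt(abs(angle_diff(atan2(v[2], v[1]), al)), 5 * pi / 180)
  # axis standard deviations within 5% of sqrt(gamma / lambda)
  expect_lt(abs(sqrt(eg$values[1]) / sqrt(0.05 / 1) - 1), 0.05)
  expect_lt(abs(sqrt(eg$values[2]) / sqrt(0.05 / 10) - 1), 0.05)
})

test_that("demand state is continuous across epoch switches", {
  sched <- variance_schedule(c(0.01, 0.2), duration = 50, dt = 0.01)
  dem <- simulate_demand(sched, seed = 9)
  k <- max(which(dem$epoch == 1))
  jump <- abs(dem$D[k + 1, 1] - dem$D[k, 1])
  # one Euler step: drift + noise of the *new* epoch
  expect_lt(jump, abs(dem$D[k, 1] - 1) * 0.01 + 6 * sqrt(2 * 0.2 * 0.01))
})

test_that("positivity guard is inactive for the default parameters", {
  dem <- simulate_demand(ou_params(), seed = 2, duration = 2000)
  expect_identical(dem$clamp_count, 0)
  expect_true(all(dem$D >= 1e-2))
})

test_that("trajectory CSV round-trips with its JSON sidecar", {
  sched <- epoch_schedule(list(env2d(0.02, dt = 5e-3),
                               env2d(0.08, pi / 8, dt = 5e-3)),
                          c(10, 15))
  dem <- simulate_demand(sched, seed = 21)
  path <- file.path(tempdir(), "traj.csv")
  write_demand(dem, path)
  back <- read_demand(path)
  expect_equal(back$D, dem$D, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$seed, dem$seed)
  expect_identical(back$epoch, as.integer(dem$epoch))
  expect_equal(back$schedule$params[[2]]$M, dem$schedule$params[[2]]$M)
  unlink(c(path, paste0(path, ".json")))
})
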