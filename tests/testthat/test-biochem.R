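test_that("allosteric Hill branches half-saturate at their constants", {
  # with the repressor branch off, quasi-steady x = ap/D; choose D so that
  # x sits exactly at c_plus: the activation term is then 1/2 of maximal
  pars <- allosteric_params()
  dem <- static_demand(1 / pars$c_plus, duration = 0.02, dt = 0.01)
  sim <- simulate_allosteric(dem, pars, learning = FALSE, a0 = c(1, 0))
  expect_equal(sim$x[1], pars$c_plus)
  # one explicit-Euler step of the activator from the half-saturated state
  dap <- sim$a_plus[2] - sim$a_plus[1]
  expect_equal(dap, 0.01 / pars$tau_a * 1 * (0.5 - pars$kappa_plus),
               tolerance = 1e-12)
})

test_that("allosteric circuit reaches a demand-independent homeostatic level", {
  for (lev in c(1, 3)) {
    dem <- static_demand(lev, duration = 3000, dt = 0.01)
    sim <- simulate_allosteric(dem, learning = TRUE, record_every = 64L)
    n <- length(sim$x)
    expect_lt(abs(mean(sim$x[round(0.9 * n):n]) - 1), 0.02)
  }
})

test_that("allosteric pair learns while its single-branch analogue degrades", {
  sched <- variance_schedule(c(0.01, 0.16), duration = 1500, dt = 1e-3)
  dem <- simulate_demand(sched, seed = 8)
  on <- simulate_allosteric(dem, learning = TRUE, discard = 0.5,
                            record_every = 64L)
  off <- simulate_allosteric(dem, learning = FALSE, discard = 0.5,
                             record_every = 64L)
  # learning: both enzymes upregulate with fluctuation strength
  asum <- on$epoch_stats$mean_a_plus + on$epoch_stats$mean_a_minus
  expect_gt(asum[2], asum[1])
  # homeostatic error: bounded growth with learning, steep growth without
  fold_on <- on$epoch_stats$mse_x[2] / on$epoch_stats$mse_x[1]
  fold_off <- off$epoch_stats$mse_x[2] / off$epoch_stats$mse_x[1]
  expect_lt(fold_on, 0.4 * fold_off)
  expect_lt(on$epoch_stats$mse_x[2], off$epoch_stats$mse_x[2])
})

test_that("bifunctional Hill partition conserves the total enzyme", {
  sched <- variance_schedule(c(0.02, 0.08), duration = 300, dt = 1e-3)
  dem <- simulate_demand(sched, seed = 12)
  sim <- simulate_bifunctional(dem, record_every = 16L)
  expect_equal(sim$a_plus + sim$a_minus, sim$A, tolerance = 1e-12)
  expect_true(all(sim$a_plus >= 0 & sim$a_plus <= sim$A))
  # half point: x = c gives a+ = A/2
  i <- which.min(abs(sim$x - bifunctional_params()$c))
  expect_lt(abs(sim$x[i] - 1), 0.05)
  expect_lt(abs(sim$a_plus[i] / sim$A[i] - 0.5), 0.05)
})

test_that("with negligible production control the enzyme decays exponentially", {
  pars <- bifunctional_params(beta = 1e-12, f0 = 1e-12, kappa = 0.05,
                              tau_A = 10)
  dem <- static_demand(1, duration = 500, dt = 0.01)
  sim <- simulate_bifunctional(dem, pars, A0 = 2, record_every = 10L)
  # A(t) ~ A0 exp(-kappa t / tau_A)
  expect_equal(sim$A[length(sim$A)],
               2 * exp(-pars$kappa * 500 / pars$tau_A), tolerance = 0.01)
})

test_that("bifunctional circuit holds x at the set point for static demand", {
  dem <- static_demand(1, duration = 500, dt = 0.01)
  sim <- simulate_bifunctional(dem, record_every = 10L)
  expect_lt(max(abs(sim$x - 1)), 1e-6)
})

test_that("bifunctional enzyme level tracks fluctuation strength", {
  sched <- variance_schedule(c(0.01, 0.16), duration = 1500, dt = 1e-3)
  dem <- simulate_demand(sched, seed = 13)
  on <- simulate_bifunctional(dem, learning = TRUE, discard = 0.5,
                              record_every = 64L)
  off <- simulate_bifunctional(dem, learning = FALSE, discard = 0.5,
                               record_every = 64L)
  expect_gt(on$epoch_stats$mean_A[2], on$epoch_stats$mean_A[1])
  fold_on <- on$epoch_stats$mse_x[2] / on$epoch_stats$mse_x[1]
  fold_off <- off$epoch_stats$mse_x[2] / off$epoch_stats$mse_x[1]
  expect_lt(fold_on, 0.4 * fold_off)
})

test_that("bifunctional responsiveness scales with total enzyme level", {
  # demand-buffering gain: the steady-state shift of x for a small demand
  # step is inversely proportional to A at the operating point
  shift <- function(A) {
    pars <- bifunctional_params(kappa = 0.01, f0 = 0.01 * A)
    up <- simulate_bifunctional(static_demand(1.05, duration = 60, dt = 0.01),
                                pars, learning = FALSE)
    dn <- simulate_bifunctional(static_demand(0.95, duration = 60, dt = 0.01),
                                pars, learning = FALSE)
    up$x[length(up$x)] - dn$x[length(dn$x)]
  }
  expect_equal(shift(5) / shift(10), 2, tolerance = 0.15)
})
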