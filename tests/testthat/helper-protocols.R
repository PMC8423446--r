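# Shared small helpers for protocol-style tests.

# single-epoch 2D environment of the correlated-input protocols
env2d <- function(gamma, alpha = pi / 4, lambda1 = 10, lambda2 = 1,
                  dt = 1e-3) {
  ou_params(dbar = c(1, 1), M = anisotropy_matrix(alpha, lambda1, lambda2),
            gamma = gamma, dt = dt)
}

# static (noise-free) demand at a constant level
static_demand <- function(level = 1, duration = 200, dt = 0.01, nx = 1) {
  simulate_demand(ou_params(dbar = rep(level, nx), gamma = 0, dt = dt),
                  seed = 1, duration = duration)
}

# smallest angular difference modulo pi
angle_diff <- function(a, b) ((a - b + pi / 2) %% pi) - pi / 2

# (performance, cip) of a circuit run on a single-epoch demand
run_point <- function(spec, dem, discard = 0.5) {
  circ <- if (spec$type == "sepi") {
    simulate_sepi(dem, spec$params, discard = discard, record_every = 256L)
  } else {
    simulate_learning(dem, spec$geometry, spec$params, discard = discard,
                      record_every = 256L)
  }
  c(performance = circ$epoch_stats$performance[1],
    cip = circ$epoch_stats$cip[1])
}
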