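#' Circuit specification for sweeps
#'
#' A lightweight description of a circuit variant (family, geometry,
#' parameters) used by the sweep drivers, which simulate every variant on the
#' same demand realizations (common random numbers) for sharp paired
#' comparisons.
#'
#' @param type `"learning"` or `"sepi"`.
#' @param name label used in sweep output.
#' @param geometry a [regulator_geometry()] (learning circuits only).
#' @param params a [learning_params()].
#' @return Object of class `circuit_spec`.
#' @export
circuit_spec <- function(type = c("learning", "sepi"), name = type,
                         geometry = NULL, params = learning_params()) {
  type <- match.arg(type)
  if (type == "learning" && is.null(geometry))
    stop("learning circuits need a geometry")
  structure(list(type = type, name = name, geometry = geometry,
                 params = params),
            class = "circuit_spec")
}

.run_spec <- function(spec, demand, discard, record_every = 256L) {
  if (spec$type == "sepi")
    simulate_sepi(demand, spec$params, discard, record_every)
  else
    simulate_learning(demand, spec$geometry, spec$params, discard,
                      record_every)
}

.default_specs <- function(kappa = 0.03) {
  list(circuit_spec("learning", "learning_na5", regulator_geometry(5, 2),
                    learning_params(kappa = kappa)),
       circuit_spec("learning", "learning_na4", regulator_geometry(4, 2),
                    learning_params(kappa = kappa)),
       circuit_spec("sepi", "sepi"))
}

#' Fluctuation-strength sweep
#'
#' Simulates each circuit variant against single-epoch demand realizations
#' over a grid of fluctuation strengths (two-dimensional correlated input with
#' dominant direction `alpha` and anisotropy `lambda1/lambda2`), and records
#' per-run performance and Control Input Power, optionally with the
#' matched-CIP theoretical ceiling.
#'
#' @param gammas fluctuation strengths.
#' @param specs list of [circuit_spec()]s (default: 5- and 4-regulator
#'   learning circuits and SEPI).
#' @param alpha dominant fluctuation direction.
#' @param lambda1,lambda2 stiffness eigenvalues.
#' @param duration run length per grid point (time units).
#' @param dt integration step.
#' @param discard transient fraction discarded.
#' @param seeds one simulation per seed per grid point; circuits share
#'   demand realizations.
#' @param with_ceiling attach the full-knowledge ceiling at each run's CIP.
#' @return data.frame: `gamma`, `circuit`, `seed`, `performance`, `cip`
#'   (+ `ceiling`).
#' @rdname sweeps
#' @export
sweep_gamma <- function(gammas, specs = .default_specs(), alpha = pi / 4,
                        lambda1 = 10, lambda2 = 1, duration = 4000,
                        dt = 1e-3, discard = 0.5, seeds = 1:3,
                        with_ceiling = FALSE) {
  rows <- list()
  for (g in gammas) {
    env <- ou_params(dbar = c(1, 1),
                     M = anisotropy_matrix(alpha, lambda1, lambda2),
                     gamma = g, dt = dt)
    curve <- if (with_ceiling) ceiling_curve(env) else NULL
    for (s in seeds) {
      dem <- simulate_demand(env, seed = s, duration = duration)
      for (spec in specs) {
        circ <- .run_spec(spec, dem, discard)
        row <- data.frame(gamma = g, circuit = spec$name, seed = s,
                          performance = circ$epoch_stats$performance[1],
                          cip = circ$epoch_stats$cip[1])
        if (with_ceiling)
          row$ceiling <- ceiling_at_cip(env, row$cip, curve = curve)
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' @details `sweep_anisotropy()` varies the anisotropy (correlation strength)
#'   at fixed per-component demand variance: the stiffness eigenvalues are
#'   rescaled so that the stationary variance of each component stays at its
#'   reference value while the correlation between the two demands changes.
#' @param anisotropies eigenvalue ratios `lambda1/lambda2 >= 1`.
#' @param gamma fluctuation strength (held constant across the anisotropy
#'   sweep).
#' @rdname sweeps
#' @export
sweep_anisotropy <- function(anisotropies, gamma = 0.05,
                             specs = .default_specs(), alpha = pi / 4,
                             duration = 4000, dt = 1e-3, discard = 0.5,
                             seeds = 1:3) {
  # reference per-component variance: that of the (10, 1) pair
  c0 <- (1 / 10 + 1 / 1) / 2
  rows <- list()
  for (r in anisotropies) {
    if (r < 1) stop("anisotropy must be >= 1")
    lambda2 <- (1 + 1 / r) / (2 * c0)
    lambda1 <- r * lambda2
    env <- ou_params(dbar = c(1, 1),
                     M = anisotropy_matrix(alpha, lambda1, lambda2),
                     gamma = gamma, dt = dt)
    for (s in seeds) {
      dem <- simulate_demand(env, seed = s, duration = duration)
      for (spec in specs) {
        circ <- .run_spec(spec, dem, discard)
        rows[[length(rows) + 1]] <-
          data.frame(anisotropy = r, circuit = spec$name, seed = s,
                     performance = circ$epoch_stats$performance[1],
                     cip = circ$epoch_stats$cip[1])
      }
    }
  }
  do.call(rbind, rows)
}

#' @details `ablation_grid()` scores learning-circuit variants over a grid of
#'   regulator counts and nonlinearity strengths, with or without
#'   self-activation, against the SEPI baseline on the same demand
#'   realizations; performance is averaged over dominant-direction angles.
#'   `gain` is the circuit performance minus the SEPI performance (positive =
#'   better tracking than SEPI).
#' @param na_values regulator counts (2-dimensional input; `Na = 2` uses the
#'   end-product-inhibition arrangement).
#' @param d_values nonlinearity thresholds (`0` = strong rectifier, `-10`
#'   effectively linear).
#' @param self_activation logical vector of variants to include.
#' @param alphas dominant-direction angles averaged over.
#' @param kappa degradation rate for all learning variants.
#' @rdname sweeps
#' @export
ablation_grid <- function(na_values = c(2, 3, 5), d_values = c(0, -10),
                          self_activation = c(TRUE, FALSE),
                          alphas = c(0, pi / 8, pi / 4, 3 * pi / 8, pi / 2),
                          gamma = 0.05, lambda1 = 10, lambda2 = 1,
                          duration = 3000, dt = 1e-3, discard = 0.5,
                          kappa = 0.03, seeds = 1L) {
  grid <- expand.grid(na = na_values, d = d_values,
                      self_activation = self_activation)
  acc <- vector("list", nrow(grid))
  sepi_perf <- c()
  for (al in alphas) {
    env <- ou_params(dbar = c(1, 1),
                     M = anisotropy_matrix(al, lambda1, lambda2),
                     gamma = gamma, dt = dt)
    for (s in seeds) {
      dem <- simulate_demand(env, seed = s, duration = duration)
      sp <- simulate_sepi(dem, discard = discard, record_every = 256L)
      sepi_perf <- c(sepi_perf, sp$epoch_stats$performance[1])
      for (k in seq_len(nrow(grid))) {
        geom <- regulator_geometry(grid$na[k], 2)
        pars <- learning_params(kappa = kappa, d = grid$d[k],
                                self_activation = grid$self_activation[k])
        circ <- simulate_learning(dem, geom, pars, discard = discard,
                                  record_every = 256L)
        acc[[k]] <- rbind(acc[[k]],
                          data.frame(alpha = al, seed = s,
                                     performance =
                                       circ$epoch_stats$performance[1],
                                     sepi = sp$epoch_stats$performance[1]))
      }
    }
  }
  out <- grid
  out$performance <- vapply(acc, function(d) mean(d$performance), 1)
  out$sepi <- mean(sepi_perf)
  out$gain <- out$performance - out$sepi
  out$gain_se <- vapply(acc, function(d) {
    g <- d$performance - d$sepi
    stats::sd(g) / sqrt(length(g))
  }, 1)
  out
}

#' Run a described sweep
#'
#' Dispatcher over the sweep drivers: `spec$type` selects
#' `"gamma"` ([sweep_gamma()]), `"anisotropy"` ([sweep_anisotropy()]) or
#' `"ablation"` ([ablation_grid()]); the remaining elements of `spec` are
#' passed through as arguments.
#'
#' @param spec a list with a `type` element and driver arguments.
#' @return The corresponding driver's data.frame.
#' @export
run_sweep <- function(spec) {
  if (is.null(spec$type) ||
      !spec$type %in% c("gamma", "anisotropy", "ablation"))
    stop("sweep spec must name a type: gamma, anisotropy or ablation")
  fn <- switch(spec$type, gamma = sweep_gamma, anisotropy = sweep_anisotropy,
               ablation = ablation_grid)
  do.call(fn, spec[setdiff(names(spec), "type")])
}
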