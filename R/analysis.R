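#' Per-epoch tracking performance
#'
#' Performance is the negated time-averaged mismatch
#' \eqn{-\langle \sum_i (P_i - D_i)^2 \rangle}, computed per epoch over the
#' retained part (the first `discard` fraction of each epoch is treated as the
#' adaptation transient and dropped). Always `<= 0`; 0 means perfect
#' tracking.
#'
#' @param circuit a `circuit_trajectory` (stored at full resolution or
#'   thinned; the stored samples must lie on the demand grid).
#' @param demand the `demand_trajectory` that drove the circuit.
#' @param discard fraction of each epoch discarded, `0 <= discard < 1`.
#' @return Named numeric vector, one performance value per epoch.
#' @export
performance <- function(circuit, demand, discard = 0.3) {
  al <- .aligned(circuit, demand)
  vapply(seq_len(max(al$epoch)), function(e) {
    rows <- .retained_rows(al$epoch, e, discard)
    -mean(rowSums((al$P[rows, , drop = FALSE] -
                     al$D[rows, , drop = FALSE])^2))
  }, 1)
}

#' Per-epoch Control Input Power
#'
#' The Control Input Power of a simulated circuit is
#' \eqn{T^{-1}\int_0^T \|\dot P\|^2 dt} with \eqn{\dot P} estimated by first
#' differences on the simulation grid, transient discarded per epoch.
#'
#' @inheritParams performance
#' @return Named numeric vector, one CIP value per epoch.
#' @export
control_input_power <- function(circuit, demand, discard = 0.3) {
  al <- .aligned(circuit, demand)
  h <- circuit$dt * circuit$record_every
  vapply(seq_len(max(al$epoch)), function(e) {
    rows <- .retained_rows(al$epoch, e, discard)
    dP <- diff(al$P[rows, , drop = FALSE]) / h
    mean(rowSums(dP^2))
  }, 1)
}

.aligned <- function(circuit, demand) {
  stopifnot(inherits(circuit, "circuit_trajectory"),
            inherits(demand, "demand_trajectory"))
  idx <- round(circuit$times / demand$dt)
  if (any(idx < 1) || any(idx > nrow(demand$D)) ||
      max(abs(demand$times[idx] - circuit$times)) > 1e-9)
    stop("circuit and demand grids are misaligned")
  list(P = circuit$P, D = demand$D[idx, , drop = FALSE],
       epoch = circuit$epoch)
}

.retained_rows <- function(epoch, e, discard) {
  stopifnot(discard >= 0, discard < 1)
  rows <- which(epoch == e)
  rows[rows - rows[1] + 1 > ceiling(discard * length(rows))]
}

#' Per-epoch performance report
#'
#' Bundles per-epoch performance, Control Input Power and mean regulator
#' activities with the provenance needed to regenerate them.
#'
#' @inheritParams performance
#' @return A `performance_report` data.frame with one row per epoch and
#'   attributes `seed`, `discard`, `kind`.
#' @export
performance_report <- function(circuit, demand, discard = 0.3) {
  perf <- performance(circuit, demand, discard)
  cip <- control_input_power(circuit, demand, discard)
  al <- .aligned(circuit, demand)
  ma <- t(vapply(seq_along(perf), function(e) {
    colMeans(circuit$a[.retained_rows(al$epoch, e, discard), , drop = FALSE])
  }, numeric(ncol(circuit$a))))
  colnames(ma) <- paste0("mean_a_", seq_len(ncol(ma)))
  out <- data.frame(epoch = seq_along(perf), performance = perf, cip = cip, ma)
  attr(out, "seed") <- demand$seed
  attr(out, "discard") <- discard
  attr(out, "kind") <- circuit$kind
  class(out) <- c("performance_report", class(out))
  out
}

#' Finite-difference responsiveness estimate
#'
#' Estimates the responsiveness matrix \eqn{R_{ij} = d\dot P_i/dD_j} by
#' central finite differences of the closed-form production rate of change
#' ([circuit_pdot()]) with respect to each demand component. When a
#' perturbation crosses the rectifier kink (the active branch changes between
#' the two sides), the affected column is flagged and a one-sided difference
#' from the unperturbed branch is used.
#'
#' @param a activity vector at the operating point.
#' @param D demand vector at the operating point.
#' @param geometry a [regulator_geometry()].
#' @param params a [learning_params()].
#' @param delta relative perturbation size.
#' @return Object of class `responsiveness_estimate`: list with the matrix
#'   `R`, `method = "finite-difference"`, logical `kink` per demand component,
#'   and `delta`.
#' @seealso [responsiveness_analytic()], [learned_angle()]
#' @export
responsiveness_empirical <- function(a, D, geometry,
                                     params = learning_params(),
                                     delta = 1e-4) {
  D <- as.numeric(D)
  nx <- length(D)
  base <- circuit_pdot(a, D, geometry, params)
  R <- matrix(0, nx, nx)
  kink <- logical(nx)
  for (j in seq_len(nx)) {
    h <- delta * max(abs(D[j]), 1)
    up <- D; up[j] <- up[j] + h
    dn <- D; dn[j] <- dn[j] - h
    pu <- circuit_pdot(a, up, geometry, params)
    pd <- circuit_pdot(a, dn, geometry, params)
    if (identical(pu$branch, pd$branch)) {
      R[, j] <- (pu$pdot - pd$pdot) / (2 * h)
    } else {
      kink[j] <- TRUE
      side <- if (identical(pu$branch, base$branch)) pu else pd
      sgn <- if (identical(pu$branch, base$branch)) 1 else -1
      R[, j] <- sgn * (side$pdot - base$pdot) / h
    }
  }
  structure(list(R = R, method = "finite-difference", kink = kink,
                 delta = delta),
            class = "responsiveness_estimate")
}

#' @export
print.responsiveness_estimate <- function(x, ...) {
  cat("Responsiveness estimate (", x$method, ")\n", sep = "")
  print(signif(x$R, 4))
  if (any(x$kink)) cat("rectifier kink crossed in column(s):",
                       which(x$kink), "\n")
  invisible(x)
}

#' Learned angle: direction of the dominant responsiveness eigenvector
#'
#' For a two-dimensional circuit the direction of largest responsiveness is
#' the dominant eigenvector of the (symmetric) responsiveness matrix; its
#' angle, reported modulo pi, is the circuit's learned estimate of the
#' dominant fluctuation direction. When the eigenvalue gap is below
#' `tol * trace` the direction is undefined (isotropic responsiveness) and
#' `NA` is returned with attribute `undefined = TRUE`.
#'
#' @param R 2x2 responsiveness matrix (a `responsiveness_estimate` is
#'   accepted). Non-symmetric input is symmetrized with a warning.
#' @param tol relative eigenvalue-gap tolerance.
#' @return Angle in `[0, pi)`, or `NA` with attribute `undefined`.
#' @export
learned_angle <- function(R, tol = 1e-6) {
  if (inherits(R, "responsiveness_estimate")) R <- R$R
  R <- as.matrix(R)
  stopifnot(nrow(R) == 2, ncol(R) == 2)
  if (max(abs(R - t(R))) > 1e-8 * max(1, max(abs(R)))) {
    warning("responsiveness matrix is not symmetric; symmetrizing")
    R <- (R + t(R)) / 2
  }
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  gap <- eg$values[1] - eg$values[2]
  if (!is.finite(gap) || gap < tol * max(abs(sum(diag(R))), .Machine$double.eps))
    return(structure(NA_real_, undefined = TRUE))
  v <- eg$vectors[, 1]
  atan2(v[2], v[1]) %% pi
}

#' Per-epoch responsiveness and learned angle of a simulated circuit
#'
#' Applies the analytic responsiveness to the time-averaged (post-transient)
#' activities of each epoch and extracts the learned angle.
#'
#' @param circuit a learning `circuit_trajectory` (from
#'   [simulate_learning()]).
#' @return data.frame with one row per epoch: `epoch`, `learned_angle`,
#'   `eigen_gap`, and the matrix entries `R11`, `R12`, `R22`.
#' @export
responsiveness_epochs <- function(circuit) {
  stopifnot(inherits(circuit, "circuit_trajectory"),
            circuit$kind == "learning")
  geom <- circuit$geometry
  do.call(rbind, lapply(seq_len(nrow(circuit$mean_a)), function(e) {
    R <- responsiveness_analytic(circuit$mean_a[e, ], geom, circuit$params)
    eg <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    ang <- learned_angle(R)
    data.frame(epoch = e, learned_angle = as.numeric(ang),
               eigen_gap = eg[1] - eg[2],
               R11 = R[1, 1], R12 = R[1, 2], R22 = R[2, 2])
  }))
}

#' Minimal fluctuation strength that engages learning
#'
#' The learning mechanism engages when fluctuations are strong enough that
#' more than `Nx` regulators sustain activity against degradation. The
#' detector starts all activities at the floor, simulates a single epoch, and
#' declares a regulator active when its time-averaged activity over the final
#' half of the run exceeds `10 * a_floor`; `gamma_min` is found by bisection
#' on a log scale. All bisection evaluations share one seed (common random
#' numbers).
#'
#' @param geometry a [regulator_geometry()].
#' @param params a [learning_params()]; its `kappa` is overridden by the
#'   `kappa` argument.
#' @param env_template an [ou_params()] providing the mean, stiffness and time
#'   step (its `gamma` is the swept quantity).
#' @param kappa degradation rate at which to locate the threshold
#'   (`kappa > 0`; `kappa = 0` returns the lower bracket edge).
#' @param bracket search interval for gamma.
#' @param duration epoch length for each detector run (time units).
#' @param iters bisection iterations.
#' @param seed seed shared by all evaluations.
#' @return The detected `gamma_min` (geometric midpoint of the final
#'   bracket).
#' @export
gamma_threshold <- function(geometry, params = learning_params(),
                            env_template = NULL, kappa = params$kappa,
                            bracket = c(1e-6, 0.5), duration = 2000,
                            iters = 12, seed = 1) {
  if (is.null(env_template))
    env_template <- ou_params(dbar = rep(1, geometry$n_inputs),
                              M = anisotropy_matrix(pi / 4),
                              gamma = 0.01, dt = 5e-3)
  if (kappa < 0) stop("kappa must be >= 0")
  pars <- learning_params(tau_a = params$tau_a, kappa = kappa, d = params$d,
                          self_activation = params$self_activation,
                          a_floor = params$a_floor, p_floor = params$p_floor,
                          a0 = params$a_floor)
  nx <- geometry$n_inputs
  engaged <- function(g) {
    env <- ou_params(dbar = env_template$dbar, M = env_template$M,
                     gamma = g, dt = env_template$dt)
    dem <- simulate_demand(env, seed = seed, duration = duration)
    # the floor-start makes early production-floor notes routine; silence them
    circ <- suppressMessages(simulate_learning(dem, geometry, pars,
                                               discard = 0.5,
                                               record_every = 64L))
    act <- circ$mean_a[1, ]
    # a non-finite average means the multiplicative growth overflowed,
    # which only happens well above threshold
    sum(act > 10 * pars$a_floor | !is.finite(act)) > nx
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (engaged(lo)) return(lo)
  if (!engaged(hi))
    stop("no threshold found in bracket [", format(lo), ", ", format(hi),
         "]: learning never engages at the bracket top")
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (engaged(mid)) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}
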