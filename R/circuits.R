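#' Regulator geometry: the constant direction matrix sigma
#'
#' Each of the `Na` regulators is a unit vector \eqn{\sigma_\mu} in demand
#' space; its components set how strongly regulator \eqn{a_\mu} activates
#' (positive) or represses (negative) the synthesis of each metabolite. In two
#' dimensions a regulator is fully characterized by an angle on the unit
#' circle.
#'
#' Defaults: for one metabolite and two regulators, the activator/repressor
#' pair \eqn{\sigma = (+1), (-1)}; for two metabolites, `Na = 2` uses the
#' end-product-inhibition arrangement (angles 0 and \eqn{\pi/2}, one regulator
#' per metabolite) and `Na >= 3` uses equally spaced angles
#' \eqn{\theta_\mu = 2\pi(\mu-1)/N_a} -- in particular `Na = 4` forms two
#' independent activator/repressor pairs, one per input.
#'
#' Mean-matching requires the mean demand to lie in the cone positively
#' spanned by the rows; a warning is emitted otherwise.
#'
#' @param n_regulators number of regulators `Na >= 1`.
#' @param n_inputs demand dimension (1 or 2; higher dimensions require an
#'   explicit `sigma`).
#' @param angles optional regulator angles (radians, `n_inputs == 2` only).
#' @param sigma optional explicit `Na x Nx` matrix; rows are normalized to
#'   unit length.
#' @param dbar mean demand used for the positive-span check.
#' @return Object of class `regulator_geometry` with elements `sigma`,
#'   `angles` (2-D only), `n_regulators`, `n_inputs`.
#' @examples
#' regulator_geometry(2, 1)            # activator/repressor pair
#' regulator_geometry(5, 2)            # five equally spaced regulators
#' regulator_geometry(1, 2, angles = pi / 4)  # single co-activating regulator
#' @export
regulator_geometry <- function(n_regulators, n_inputs = 2, angles = NULL,
                               sigma = NULL, dbar = rep(1, n_inputs)) {
  na <- as.integer(n_regulators)
  nx <- as.integer(n_inputs)
  if (na < 1) stop("need at least one regulator")
  if (is.null(sigma)) {
    if (nx == 1) {
      if (!is.null(angles)) stop("angles only apply to two inputs")
      sigma <- matrix(rep_len(c(1, -1), na), ncol = 1)
    } else if (nx == 2) {
      if (is.null(angles)) {
        angles <- if (na == 2) c(0, pi / 2) else 2 * pi * (seq_len(na) - 1) / na
      }
      if (length(angles) != na) stop("need one angle per regulator")
      sigma <- cbind(cos(angles), sin(angles))
    } else {
      stop("n_inputs > 2 requires an explicit sigma matrix")
    }
  } else {
    sigma <- as.matrix(sigma)
    if (nrow(sigma) != na || ncol(sigma) != nx)
      stop("sigma must be n_regulators x n_inputs")
    nrm <- sqrt(rowSums(sigma^2))
    if (any(nrm == 0)) stop("sigma rows must be nonzero")
    sigma <- sigma / nrm
    angles <- if (nx == 2) atan2(sigma[, 2], sigma[, 1]) else NULL
  }
  if (!.spans_mean(sigma, dbar))
    warning("regulator directions do not positively span the mean demand; ",
            "mean-matching is impossible for this geometry")
  structure(list(sigma = sigma, angles = angles, n_regulators = na,
                 n_inputs = nx),
            class = "regulator_geometry")
}

# can dbar be written as sigma^T c with c >= 0?
.spans_mean <- function(sigma, dbar) {
  nx <- ncol(sigma)
  if (nx == 1) return(any(sign(sigma[, 1]) == sign(dbar)))
  th <- sort(atan2(sigma[, 2], sigma[, 1]) %% (2 * pi))
  gaps <- diff(c(th, th[1] + 2 * pi))
  if (max(gaps) < pi) return(TRUE) # rows positively span the whole plane
  # otherwise the cone is the sector complementary to the largest gap
  k <- which.max(gaps)
  lo <- th[if (k == length(th)) 1 else k + 1] %% (2 * pi)
  width <- 2 * pi - max(gaps)
  a <- (atan2(dbar[2], dbar[1]) - lo) %% (2 * pi)
  a <= width + 1e-12
}

#' @export
print.regulator_geometry <- function(x, ...) {
  cat(sprintf("Regulator geometry: %d regulator(s), %d input(s)\n",
              x$n_regulators, x$n_inputs))
  if (!is.null(x$angles))
    cat("angles (deg):", format(round(x$angles * 180 / pi, 1)), "\n")
  else cat("sigma:", format(x$sigma[, 1]), "\n")
  invisible(x)
}

#' Circuit parameters for SEPI and the learning architecture
#'
#' The learning circuit couples metabolite read-out to regulator dynamics via
#' \deqn{x_i = P_i / D_i, \quad P_i = \sum_\mu \sigma_{\mu i} a_\mu, \quad
#'   \tau_a \dot a_\mu = a_\mu \max\{d, \sum_i \sigma_{\mu i}(1 - x_i)\}
#'   - \kappa a_\mu,}
#' in units where the metabolite set point and the production unit are 1.
#' Metabolites are fast relative to regulation, so \eqn{x = P/D} is enforced
#' algebraically. The SEPI baseline is the one-regulator-per-metabolite
#' linearized form \eqn{\tau_a \dot a = 1 - x} (no degradation, no
#' nonlinearity).
#'
#' Default rationale: `tau_a = 10` separates regulation from the demand
#' fluctuation timescale (1/eigenvalue of M); `d = 0` is the strong
#' nonlinearity; `kappa = 0.03` is small compared with the set point while
#' keeping the adapted regulator state resolvable on the integration grid (the
#' equilibrium tracking error, about \eqn{\kappa\sqrt{2\pi}}, must exceed the
#' per-step demand innovation \eqn{\sqrt{2\Gamma\,dt}}).
#'
#' @param tau_a regulator timescale (time units).
#' @param kappa degradation rate (dimensionless per Eq.-(4c) scaling),
#'   `kappa >= 0`.
#' @param d nonlinearity threshold, `d <= 0`; `d = 0` is the strong
#'   rectifier, large negative `d` approaches a linear circuit.
#' @param self_activation logical; when off, the multiplicative prefactor
#'   before the rectifier is omitted.
#' @param a_floor smallest allowed activity under self-activation.
#' @param p_floor production floor applied before the division by demand.
#' @param a0 initial activity per regulator; default `1/Na` for the learning
#'   circuit, the mean demand for SEPI.
#' @return Object of class `learning_params`.
#' @export
learning_params <- function(tau_a = 10, kappa = 0.03, d = 0,
                            self_activation = TRUE, a_floor = 1e-6,
                            p_floor = 1e-3, a0 = NULL) {
  if (tau_a <= 0) stop("tau_a must be > 0")
  if (kappa < 0) stop("kappa must be >= 0")
  if (d > 0) stop("d must be <= 0")
  if (a_floor <= 0) stop("a_floor must be > 0")
  structure(list(tau_a = tau_a, kappa = kappa, d = d,
                 self_activation = isTRUE(self_activation),
                 a_floor = a_floor, p_floor = p_floor, a0 = a0),
            class = "learning_params")
}

.as_circuit_trajectory <- function(res, demand, record_every, kind,
                                   extra = list()) {
  idx <- res$idx
  out <- c(list(times = demand$times[idx], a = res$a, P = res$P, x = res$x,
                epoch = demand$epoch[idx], record_every = record_every,
                dt = demand$dt, kind = kind,
                epoch_stats = data.frame(epoch = seq_along(res$perf),
                                         performance = res$perf,
                                         cip = res$cip)),
           list(mean_a = res$mean_a, mean_x = res$mean_x), extra)
  structure(out, class = "circuit_trajectory")
}

#' Simulate the simple end-product inhibition baseline
#'
#' One regulator per metabolite: \eqn{x_i = P_i/D_i}, \eqn{P_i = a_i},
#' \eqn{\tau_a \dot a_i = 1 - x_i}, integrated with explicit Euler on the
#' demand grid. The regulator timescale may be changed through `params` to
#' build responsiveness-matched comparisons.
#'
#' @param demand a `demand_trajectory`.
#' @param params a [learning_params()]; only `tau_a`, `p_floor` and `a0` are
#'   used.
#' @param discard fraction of each epoch discarded (adaptation transient) in
#'   the per-epoch summary statistics.
#' @param record_every store every k-th sample (thinning for long runs;
#'   summaries always use the full resolution).
#' @return A `circuit_trajectory` with elements `times`, `a`, `P`, `x`,
#'   `epoch` and per-epoch summaries (`epoch_stats`, `mean_a`, `mean_x`).
#' @export
simulate_sepi <- function(demand, params = learning_params(), discard = 0.3,
                          record_every = 1L) {
  stopifnot(inherits(demand, "demand_trajectory"))
  nx <- ncol(demand$D)
  a0 <- if (is.null(params$a0)) demand$schedule$params[[1]]$dbar
        else rep_len(params$a0, nx)
  res <- cpp_sim_sepi(demand$D, demand$epoch, demand$dt, params$tau_a,
                      as.numeric(a0), params$p_floor, discard,
                      as.integer(record_every))
  .as_circuit_trajectory(res, demand, record_every, "sepi",
                         list(params = params,
                              p_floor_hits = res$p_floor_hits))
}

#' Simulate the learning circuit (excess regulators, self-activation,
#' rectifying nonlinearity)
#'
#' Integrates the excess-regulator architecture (see [learning_params()]) with
#' explicit Euler, one circuit update per demand sample. With
#' `self_activation = FALSE` the multiplicative prefactor is omitted (the
#' ablation variant); activities are then affine and are not floored.
#'
#' @inheritParams simulate_sepi
#' @param geometry a [regulator_geometry()].
#' @param params a [learning_params()].
#' @return A `circuit_trajectory`; `a_floor_hits` and `p_floor_hits` count the
#'   applications of the activity and production guards.
#' @examples
#' traj <- simulate_demand(ou_params(gamma = 0.05, dt = 1e-3), seed = 1,
#'                         duration = 100)
#' circ <- simulate_learning(traj, regulator_geometry(2, 1))
#' colMeans(circ$a)
#' @export
simulate_learning <- function(demand, geometry, params = learning_params(),
                              discard = 0.3, record_every = 1L) {
  stopifnot(inherits(demand, "demand_trajectory"),
            inherits(geometry, "regulator_geometry"))
  if (geometry$n_inputs != ncol(demand$D))
    stop("geometry and demand dimensions disagree")
  na <- geometry$n_regulators
  a0 <- if (is.null(params$a0)) rep(1 / na, na) else rep_len(params$a0, na)
  res <- cpp_sim_learning(demand$D, demand$epoch, geometry$sigma, demand$dt,
                          params$tau_a, params$kappa, params$d,
                          params$self_activation, params$a_floor,
                          params$p_floor, as.numeric(a0), discard,
                          as.integer(record_every))
  if (res$p_floor_hits > 0)
    message(sprintf("production floor applied at %g sample(s)",
                    res$p_floor_hits))
  .as_circuit_trajectory(res, demand, record_every, "learning",
                         list(params = params, geometry = geometry,
                              a_floor_hits = res$a_floor_hits,
                              p_floor_hits = res$p_floor_hits))
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf("Circuit trajectory (%s): %d stored sample(s), %d epoch(s)\n",
              x$kind, nrow(x$a), max(x$epoch)))
  print(x$epoch_stats, row.names = FALSE)
  invisible(x)
}

#' Analytic responsiveness of the learning circuit
#'
#' The responsiveness is the sensitivity of the production rate of change to
#' demand, \eqn{R_{ij} = d\dot P_i / dD_j}. At the operating point
#' (\eqn{x \approx 1}, \eqn{D \approx \bar D}, rectifier on its active
#' branch) the self-activating circuit gives
#' \deqn{R = \tau_a^{-1} \sum_\mu a_\mu\, \sigma_\mu \sigma_\mu^T,}
#' a symmetric positive semi-definite matrix: activity stored in a regulator
#' makes the circuit faster along that regulator's direction. In one dimension
#' with the \eqn{\pm 1} pair this reduces to \eqn{(a_+ + a_-)/\tau_a}.
#'
#' @param a activity vector (length `Na`).
#' @param geometry a [regulator_geometry()].
#' @param params a [learning_params()] (only `tau_a` and `self_activation`
#'   are used; without self-activation the activity weights drop out and
#'   \eqn{R = \tau_a^{-1}\sum_\mu \sigma_\mu\sigma_\mu^T}).
#' @return `Nx x Nx` responsiveness matrix.
#' @seealso [responsiveness_empirical()], [learned_angle()]
#' @export
responsiveness_analytic <- function(a, geometry, params = learning_params()) {
  stopifnot(inherits(geometry, "regulator_geometry"))
  sg <- geometry$sigma
  w <- if (params$self_activation) as.numeric(a) else rep(1, nrow(sg))
  R <- crossprod(sg * w, sg) / params$tau_a
  (R + t(R)) / 2
}

#' Production rate of change at a state
#'
#' Evaluates \eqn{\dot P(a, D)} of the learning circuit in closed form (the
#' metabolite read-out is algebraic, so no integration is involved). Used by
#' the finite-difference responsiveness estimator.
#'
#' @inheritParams responsiveness_analytic
#' @param D demand vector.
#' @return List with `pdot` (length `Nx`), `adot`, and `branch` (the active
#'   branch of the rectifier per regulator: TRUE where the argument exceeds
#'   `d`).
#' @export
circuit_pdot <- function(a, D, geometry, params = learning_params()) {
  sg <- geometry$sigma
  a <- as.numeric(a)
  P <- pmax(as.vector(crossprod(sg, a)), params$p_floor)
  x <- P / as.numeric(D)
  proj <- as.vector(sg %*% (1 - x))
  branch <- proj > params$d
  drv <- pmax(proj, params$d)
  pre <- if (params$self_activation) a else rep(1, length(a))
  adot <- (pre * drv - params$kappa * a) / params$tau_a
  list(pdot = as.vector(crossprod(sg, adot)), adot = adot, branch = branch)
}
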