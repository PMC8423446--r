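#' Parameters of the Ornstein--Uhlenbeck demand process
#'
#' The environment is a demand vector \eqn{D(t)} undergoing a random walk in a
#' quadratic potential,
#' \deqn{D(t+\Delta t) = D(t) - M (D(t) - \bar D)\,\Delta t +
#'       \sqrt{2\Gamma\Delta t}\,\eta,}
#' with mean \eqn{\bar D}, symmetric positive-definite stiffness matrix
#' \eqn{M} (units 1/time), scalar fluctuation strength \eqn{\Gamma}
#' (demand^2/time) and i.i.d. standard-normal increments \eqn{\eta}. The
#' stationary distribution is Gaussian with covariance \eqn{\Gamma M^{-1}}:
#' the principal fluctuation axes are the eigenvectors of \eqn{M}, with
#' standard deviations \eqn{\sqrt{\Gamma/\lambda_i}}.
#'
#' @param dbar mean demand vector (default 1, one metabolite).
#' @param M symmetric positive-definite stiffness matrix; scalar allowed for
#'   one dimension. Default: identity rate 1.
#' @param gamma fluctuation strength \eqn{\Gamma \ge 0}. The default 0.01 keeps
#'   the demand comfortably positive so the positivity guard is inactive.
#' @param dt Euler--Maruyama time step. Must satisfy
#'   `dt * max(eigen(M)) < 0.1` (accuracy/stability guard).
#' @return An object of class `ou_params`.
#' @seealso [simulate_demand()], [stationary_stats()], [anisotropy_matrix()]
#' @examples
#' ou_params(gamma = 0.05)
#' ou_params(dbar = c(1, 1), M = anisotropy_matrix(pi / 4), gamma = 0.05)
#' @export
ou_params <- function(dbar = 1, M = NULL, gamma = 0.01, dt = 0.01) {
  dbar <- as.numeric(dbar)
  nx <- length(dbar)
  if (is.null(M)) M <- diag(nx)
  if (is.null(dim(M))) M <- diag(as.numeric(M), nx)
  M <- as.matrix(M)
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
    stop("M must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("M must be positive definite")
  if (gamma < 0) stop("gamma must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (dt * max(ev) >= 0.1)
    stop("dt * max eigenvalue of M must be < 0.1 (choose a smaller dt)")
  structure(list(dbar = dbar, M = M, gamma = gamma, dt = dt, nx = nx),
            class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat(sprintf("OU demand process: %d dimension(s), gamma = %g, dt = %g\n",
              x$nx, x$gamma, x$dt))
  cat("mean:", format(x$dbar), "\n")
  cat("stiffness eigenvalues:",
      format(eigen(x$M, symmetric = TRUE, only.values = TRUE)$values), "\n")
  invisible(x)
}

#' Two-dimensional anisotropy matrix with a prescribed dominant direction
#'
#' Builds \eqn{M = R(\alpha)\,\mathrm{diag}(\lambda_2, \lambda_1)\,R(\alpha)^T}
#' with \eqn{R} a rotation by `alpha`, so that the low-stiffness eigenvector
#' (eigenvalue `lambda2`, the direction of the largest demand spread
#' \eqn{\sqrt{\Gamma/\lambda_2}}) points along the angle `alpha`.
#'
#' @param alpha angle of the dominant fluctuation direction, radians.
#' @param lambda1 larger stiffness eigenvalue (rate of the tight direction).
#' @param lambda2 smaller stiffness eigenvalue; `lambda1 >= lambda2 > 0`.
#'   The ratio `lambda1/lambda2` is the fluctuation anisotropy (10 by default).
#' @return A 2x2 symmetric matrix with eigenvalues `lambda1`, `lambda2`.
#' @examples
#' anisotropy_matrix(0)          # diag(1, 10): dominant axis = x-axis
#' anisotropy_matrix(pi / 4)     # [[5.5, -4.5], [-4.5, 5.5]]
#' @export
anisotropy_matrix <- function(alpha, lambda1 = 10, lambda2 = 1) {
  if (lambda2 <= 0 || lambda1 < lambda2)
    stop("need lambda1 >= lambda2 > 0")
  R <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2, 2)
  R %*% diag(c(lambda2, lambda1)) %*% t(R)
}

#' Epoch schedule for the demand process
#'
#' An epoch is a period over which the fluctuation structure (`M`, `gamma`) is
#' constant; epochs are long compared to the circuit's adaptation time. The
#' demand state is continuous across epoch switches -- only the statistics
#' change.
#'
#' @param params a single `ou_params` or a list of them, one per epoch. All
#'   epochs must share the dimension, mean and time step.
#' @param durations epoch durations in time units (recycled to the number of
#'   epochs).
#' @return An object of class `epoch_schedule`.
#' @seealso [variance_schedule()], [angle_schedule()]
#' @export
epoch_schedule <- function(params, durations) {
  if (inherits(params, "ou_params")) params <- list(params)
  if (!all(vapply(params, inherits, TRUE, "ou_params")))
    stop("params must be ou_params objects")
  durations <- rep_len(as.numeric(durations), length(params))
  if (any(durations <= 0)) stop("durations must be > 0")
  nx <- vapply(params, function(p) p$nx, 1L)
  dt <- vapply(params, function(p) p$dt, 1)
  if (length(unique(nx)) != 1L || length(unique(dt)) != 1L)
    stop("all epochs must share the demand dimension and time step")
  structure(list(params = params, durations = durations,
                 nx = nx[1], dt = dt[1]),
            class = "epoch_schedule")
}

#' @export
print.epoch_schedule <- function(x, ...) {
  cat(sprintf("Epoch schedule: %d epoch(s), %d dimension(s), dt = %g\n",
              length(x$params), x$nx, x$dt))
  for (e in seq_along(x$params))
    cat(sprintf("  epoch %d: duration %g, gamma %g\n", e, x$durations[e],
                x$params[[e]]$gamma))
  invisible(x)
}

#' Stepwise-variance and rotating-anisotropy schedules
#'
#' `variance_schedule()` steps the fluctuation strength `gamma` through a
#' ladder of values at fixed `M` (the one-dimensional learning protocol);
#' `angle_schedule()` rotates the dominant fluctuation direction through a
#' sequence of angles at fixed eigenvalues and `gamma` (the two-dimensional
#' angle-learning protocol).
#'
#' @param gammas fluctuation strengths, one per epoch.
#' @param duration epoch duration (time units), recycled.
#' @param dbar,M,dt forwarded to [ou_params()].
#' @return An `epoch_schedule`.
#' @rdname schedules
#' @export
variance_schedule <- function(gammas, duration = 2000, dbar = 1, M = NULL,
                              dt = 1e-3) {
  epoch_schedule(lapply(gammas, function(g)
    ou_params(dbar = dbar, M = M, gamma = g, dt = dt)), duration)
}

#' @param alphas dominant-direction angles (radians), one per epoch.
#' @param gamma fluctuation strength shared by all epochs.
#' @param lambda1,lambda2 stiffness eigenvalues, see [anisotropy_matrix()].
#' @rdname schedules
#' @export
angle_schedule <- function(alphas, duration = 3000, gamma = 0.05,
                           lambda1 = 10, lambda2 = 1, dt = 1e-3) {
  epoch_schedule(lapply(alphas, function(al)
    ou_params(dbar = c(1, 1), M = anisotropy_matrix(al, lambda1, lambda2),
              gamma = gamma, dt = dt)), duration)
}

#' Simulate an epoch-structured demand trajectory
#'
#' Integrates the demand random walk with the explicit Euler--Maruyama update
#' exactly as the model defines it, one normal draw per component per step.
#' Demands are floored at \eqn{\epsilon_D = 10^{-2}|\bar D|} component-wise
#' (the downstream circuits divide by \eqn{D}); floored points are counted in
#' `clamp_count` and the guard is inactive for the default parameter sets.
#'
#' @param schedule an [epoch_schedule()] (a bare `ou_params` is promoted to a
#'   single epoch of duration `duration`).
#' @param seed integer seed; the same `(schedule, seed)` pair reproduces the
#'   trajectory bit for bit.
#' @param duration single-epoch duration used when `schedule` is a bare
#'   `ou_params`.
#' @return An object of class `demand_trajectory`: list with `times`, matrix
#'   `D` (steps x dimensions), integer `epoch`, `seed`, `clamp_count`, `dt`,
#'   and the generating `schedule`.
#' @examples
#' traj <- simulate_demand(ou_params(gamma = 0.05, dt = 0.01), seed = 1,
#'                         duration = 50)
#' var(traj$D[, 1]) # ~ gamma / M for long runs
#' @export
simulate_demand <- function(schedule, seed, duration = 1000) {
  if (inherits(schedule, "ou_params"))
    schedule <- epoch_schedule(schedule, duration)
  if (!inherits(schedule, "epoch_schedule")) stop("invalid schedule")
  params <- schedule$params
  nx <- schedule$nx
  dt <- schedule$dt
  n_steps <- as.integer(round(schedule$durations / dt))
  M_flat <- do.call(cbind, lapply(params, function(p) p$M))
  gamma <- vapply(params, function(p) p$gamma, 1)
  dbar <- params[[1]]$dbar
  eps <- 1e-2 * max(abs(dbar))
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  res <- cpp_sim_ou(dbar, dbar, M_flat, gamma, n_steps, dt, eps)
  structure(list(times = dt * seq_len(nrow(res$D)), D = res$D,
                 epoch = res$epoch, seed = seed,
                 clamp_count = res$clamp_count, dt = dt,
                 schedule = schedule),
            class = "demand_trajectory")
}

#' @export
print.demand_trajectory <- function(x, ...) {
  cat(sprintf(paste0("Demand trajectory: %d steps, %d dimension(s), ",
                     "%d epoch(s), seed %d, %g clamped point(s)\n"),
              nrow(x$D), ncol(x$D), max(x$epoch), x$seed, x$clamp_count))
  invisible(x)
}

#' Analytic stationary statistics of the demand process
#'
#' The stationary law of the demand random walk is Gaussian with mean
#' \eqn{\bar D} and covariance \eqn{\Gamma M^{-1}}; in one dimension the
#' variance is \eqn{\Gamma/M}, and in two the standard deviations along the
#' eigenvectors of \eqn{M} are \eqn{\sqrt{\Gamma/\lambda_{1,2}}}.
#'
#' @param params an [ou_params()] object.
#' @return List with `mean` and `covariance`.
#' @export
stationary_stats <- function(params) {
  stopifnot(inherits(params, "ou_params"))
  cov <- params$gamma * solve(params$M)
  list(mean = params$dbar, covariance = (cov + t(cov)) / 2)
}

#' Write / read a demand trajectory as CSV plus JSON sidecar
#'
#' The CSV holds columns `time, epoch, D_1..D_Nx`; the sidecar
#' (`<path>.json`) records the seed, time step, positivity-clamp count and the
#' per-epoch parameters so that the trajectory is regenerable.
#'
#' @param traj a `demand_trajectory`.
#' @param path CSV file path.
#' @return `write_demand()` returns `path` invisibly; `read_demand()` returns
#'   a `demand_trajectory` (without the generating schedule object when only
#'   the sidecar metadata is available).
#' @rdname demand_io
#' @export
write_demand <- function(traj, path) {
  stopifnot(inherits(traj, "demand_trajectory"))
  df <- data.frame(time = traj$times, epoch = traj$epoch, traj$D)
  names(df)[-(1:2)] <- paste0("D_", seq_len(ncol(traj$D)))
  write.csv(df, path, row.names = FALSE)
  meta <- list(
    seed = traj$seed, dt = traj$dt, clamp_count = traj$clamp_count,
    epochs = lapply(seq_along(traj$schedule$params), function(e) {
      p <- traj$schedule$params[[e]]
      list(duration = traj$schedule$durations[e], dbar = p$dbar,
           M = as.vector(p$M), gamma = p$gamma)
    }))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname demand_io
#' @export
read_demand <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dcols <- grep("^D_", names(df))
  sched <- epoch_schedule(
    lapply(seq_len(nrow(as.data.frame(meta$epochs))), function(e) {
      ep <- meta$epochs[e, ]
      dbar <- unlist(ep$dbar)
      ou_params(dbar = dbar,
                M = matrix(unlist(ep$M), length(dbar)),
                gamma = ep$gamma, dt = meta$dt)
    }),
    vapply(seq_len(nrow(as.data.frame(meta$epochs))),
           function(e) meta$epochs[e, ]$duration, 1))
  structure(list(times = df$time, D = as.matrix(df[, dcols, drop = FALSE]),
                 epoch = as.integer(df$epoch), seed = as.integer(meta$seed),
                 clamp_count = meta$clamp_count, dt = meta$dt,
                 schedule = sched),
            class = "demand_trajectory")
}
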