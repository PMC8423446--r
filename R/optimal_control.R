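#' Continuous-time algebraic Riccati and Lyapunov solvers
#'
#' `care()` solves \eqn{A^T X + X A - X B R^{-1} B^T X + Q = 0} for the
#' stabilizing solution via the stable invariant subspace of the Hamiltonian
#' matrix; `lyap()` solves \eqn{A X + X A^T + W = 0} by the Kronecker-product
#' linear system. Both are intended for the small state dimensions of the
#' tracking problem (a handful of states), where dense eigendecomposition is
#' perfectly adequate.
#'
#' @param A,B,Q,R,W conformable matrices; `R` must be invertible and the pair
#'   `(A, B)` stabilizable.
#' @return The solution matrix.
#' @keywords internal
care <- function(A, B, Q, R) {
  n <- nrow(A)
  G <- B %*% solve(R, t(B))
  H <- rbind(cbind(A, -G), cbind(-Q, -t(A)))
  eg <- eigen(H)
  idx <- order(Re(eg$values))[seq_len(n)]
  if (any(Re(eg$values[idx]) >= -1e-12))
    stop("Riccati solve failed: Hamiltonian has no full stable subspace ",
         "(eigenvalue real parts: ",
         paste(format(sort(Re(eg$values))), collapse = ", "), ")")
  V <- eg$vectors[, idx, drop = FALSE]
  X1 <- V[seq_len(n), , drop = FALSE]
  X2 <- V[n + seq_len(n), , drop = FALSE]
  X <- Re(X2 %*% solve(X1))
  X <- (X + t(X)) / 2
  res <- t(A) %*% X + X %*% A - X %*% G %*% X + Q
  if (max(abs(res)) > 1e-6 * max(1, max(abs(Q))))
    stop("Riccati solve failed: residual ", format(max(abs(res))))
  X
}

#' @rdname care
#' @keywords internal
lyap <- function(A, W) {
  n <- nrow(A)
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  X <- matrix(solve(K, -as.vector(W)), n, n)
  (X + t(X)) / 2
}

.track_matrices <- function(env) {
  nx <- env$nx
  A <- matrix(0, 2 * nx, 2 * nx)
  A[seq_len(nx), seq_len(nx)] <- -env$M
  B <- rbind(matrix(0, nx, nx), diag(nx))
  Q <- rbind(cbind(diag(nx), -diag(nx)), cbind(-diag(nx), diag(nx)))
  W <- matrix(0, 2 * nx, 2 * nx)
  W[seq_len(nx), seq_len(nx)] <- 2 * env$gamma * diag(nx)
  list(A = A, B = B, Q = Q, W = W, nx = nx)
}

#' Optimal tracking policy for a known demand process
#'
#' Solves the stationary linear-quadratic tracking problem for the state
#' \eqn{z = (D - \bar D, P - \bar D)} with dynamics
#' \eqn{\dot D = -M (D - \bar D) + \text{noise}}, \eqn{\dot P = u} and cost
#' \eqn{\langle \|P - D\|^2 + \rho \|u\|^2 \rangle}. The control-effort
#' penalty \eqn{\rho} is the Lagrangian form of a Control Input Power
#' constraint: sweeping \eqn{\rho} traces the family of optimal behaviors
#' parameterized by CIP. The optimal feedback steers P toward the conditional
#' expectation of the future demand, so for anisotropic \eqn{M} the gain is
#' anisotropic with the same eigenvectors.
#'
#' @param env an [ou_params()] describing the believed demand process.
#' @param rho control-effort penalty, `rho > 0` (`Inf` gives the zero-gain
#'   policy that freezes P at the mean demand).
#' @return Object of class `tracking_policy` with the feedback gain `K`
#'   (control \eqn{u = -K z}), `rho` and the believed `env`.
#' @seealso [evaluate_policy()], [ceiling_at_cip()], [diagonal_env()]
#' @export
optimal_policy <- function(env, rho) {
  stopifnot(inherits(env, "ou_params"))
  m <- .track_matrices(env)
  if (is.infinite(rho)) {
    K <- matrix(0, m$nx, 2 * m$nx)
  } else {
    if (rho <= 0) stop("rho must be > 0")
    X <- care(m$A, m$B, m$Q, rho * diag(m$nx))
    K <- solve(rho * diag(m$nx), t(m$B) %*% X)
  }
  structure(list(K = K, rho = rho, env = env), class = "tracking_policy")
}

#' @export
print.tracking_policy <- function(x, ...) {
  cat(sprintf("LQ tracking policy: rho = %g, %d-dimensional demand\n",
              x$rho, x$env$nx))
  cat("gain K:\n"); print(signif(x$K, 4))
  invisible(x)
}

#' Stationary performance and Control Input Power of a policy
#'
#' Evaluates the closed loop \eqn{\dot z = (A - B K) z + \text{noise}} under a
#' (possibly different) true environment, by solving the stationary Lyapunov
#' equation. Returns the performance \eqn{-\langle\|P - D\|^2\rangle} and the
#' Control Input Power \eqn{\langle\|\dot P\|^2\rangle}. Passing
#' `true_env != policy$env` evaluates misspecified policies, e.g. one built on
#' the independence assumption of [diagonal_env()].
#'
#' @param policy a [optimal_policy()] result.
#' @param true_env the environment generating the demand (defaults to the
#'   policy's own).
#' @return Object of class `ceiling_point`: list with `cip` and
#'   `performance`.
#' @export
evaluate_policy <- function(policy, true_env = policy$env) {
  stopifnot(inherits(policy, "tracking_policy"),
            inherits(true_env, "ou_params"))
  if (true_env$nx != policy$env$nx) stop("dimension mismatch")
  m <- .track_matrices(true_env)
  Acl <- m$A - m$B %*% policy$K
  if (all(policy$K == 0)) {
    # P frozen at the mean: stationary covariance of the demand block only
    S <- matrix(0, 2 * m$nx, 2 * m$nx)
    S[seq_len(m$nx), seq_len(m$nx)] <- true_env$gamma * solve(true_env$M)
  } else {
    if (any(Re(eigen(Acl, only.values = TRUE)$values) >= 0))
      stop("closed loop is unstable under the true environment")
    S <- lyap(Acl, m$W)
  }
  structure(list(cip = sum(diag(policy$K %*% S %*% t(policy$K))),
                 performance = -sum(diag(m$Q %*% S))),
            class = "ceiling_point")
}

#' @export
print.ceiling_point <- function(x, ...) {
  cat(sprintf("ceiling point: CIP = %g, performance = %g\n",
              x$cip, x$performance))
  invisible(x)
}

#' Simulate a tracking policy on a demand trajectory
#'
#' Euler integration of \eqn{\dot P = -K z} against a stored demand
#' trajectory; the empirical (performance, CIP) cross-checks the analytic
#' Lyapunov evaluation.
#'
#' @param policy a `tracking_policy`.
#' @param demand a `demand_trajectory` from the same (or any) environment.
#' @param discard initial fraction discarded.
#' @return List with `performance`, `cip` and the production matrix `P`.
#' @export
simulate_policy <- function(policy, demand, discard = 0.1) {
  stopifnot(inherits(policy, "tracking_policy"),
            inherits(demand, "demand_trajectory"))
  D <- demand$D
  nx <- ncol(D)
  dbar <- demand$schedule$params[[1]]$dbar
  dt <- demand$dt
  n <- nrow(D)
  P <- matrix(0, n, nx)
  p <- dbar
  K <- policy$K
  for (t in seq_len(n)) {
    z <- c(D[t, ] - dbar, p - dbar)
    p <- p - as.vector(K %*% z) * dt
    P[t, ] <- p
  }
  keep <- seq.int(floor(discard * n) + 1L, n)
  dP <- diff(P[keep, , drop = FALSE]) / dt
  list(performance = -mean(rowSums((P[keep, , drop = FALSE] -
                                      D[keep, , drop = FALSE])^2)),
       cip = mean(rowSums(dP^2)), P = P)
}

#' Performance ceiling curve and matched-CIP ceiling
#'
#' `ceiling_curve()` sweeps the control-effort penalty over a log grid and
#' returns the (rho, CIP, performance) family; `ceiling_at_cip()`
#' interpolates the family's performance at a target Control Input Power. The
#' curve is the theoretical optimum a system with full knowledge of (M, Gamma)
#' can reach at the given effort budget; performance is non-decreasing in CIP.
#'
#' @param env an [ou_params()] the policies are optimized for.
#' @param true_env environment under which policies are evaluated (defaults
#'   to `env`; pass the true process to score misspecified families).
#' @param rho_range log10 limits of the penalty sweep.
#' @param n_rho number of grid points.
#' @return `ceiling_curve()`: data.frame with columns `rho`, `cip`,
#'   `performance`. `ceiling_at_cip()`: performance at the target CIP.
#' @rdname ceiling
#' @export
ceiling_curve <- function(env, true_env = env, rho_range = c(-8, 5),
                          n_rho = 80) {
  rhos <- 10^seq(rho_range[1], rho_range[2], length.out = n_rho)
  rows <- lapply(rhos, function(r) {
    pt <- tryCatch(evaluate_policy(optimal_policy(env, r), true_env),
                   error = function(e) NULL)
    if (is.null(pt)) return(NULL)
    data.frame(rho = r, cip = pt$cip, performance = pt$performance)
  })
  out <- do.call(rbind, rows)
  out[order(out$cip), ]
}

#' @param target_cip Control Input Power at which to read off the ceiling
#'   (`>= 0`).
#' @param curve optionally a precomputed [ceiling_curve()].
#' @rdname ceiling
#' @export
ceiling_at_cip <- function(env, target_cip, true_env = env,
                           rho_range = c(-8, 5), n_rho = 80, curve = NULL) {
  if (target_cip < 0) stop("target_cip must be >= 0")
  if (target_cip == 0) {
    pt <- evaluate_policy(optimal_policy(env, Inf), true_env)
    return(pt$performance)
  }
  if (is.null(curve)) curve <- ceiling_curve(env, true_env, rho_range, n_rho)
  if (target_cip < min(curve$cip) || target_cip > max(curve$cip)) {
    # extend the sweep once before giving up
    curve <- ceiling_curve(env, true_env,
                           rho_range + c(-4, 4) * sign(rho_range[2] -
                                                         rho_range[1]),
                           n_rho * 2)
    if (target_cip < min(curve$cip) || target_cip > max(curve$cip))
      stop("target CIP ", format(target_cip), " outside swept range [",
           format(min(curve$cip)), ", ", format(max(curve$cip)), "]")
  }
  stats::approx(log(curve$cip), curve$performance, xout = log(target_cip),
                ties = "ordered")$y
}

#' Independence-assuming (diagonally misspecified) environment model
#'
#' The demand model used by a system that assumes the components of D to be
#' independent: a diagonal-stiffness OU process whose per-component stationary
#' variances match the true process, \eqn{M'_{ii} = 1/(M^{-1})_{ii}}. Policies
#' optimized for this model and evaluated under the true environment give the
#' theoretical ceiling achievable without exploiting correlations.
#'
#' @param env the true [ou_params()].
#' @return An `ou_params` with diagonal stiffness.
#' @export
diagonal_env <- function(env) {
  stopifnot(inherits(env, "ou_params"))
  Minv <- solve(env$M)
  ou_params(dbar = env$dbar, M = diag(1 / diag(Minv), env$nx),
            gamma = env$gamma, dt = env$dt)
}
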