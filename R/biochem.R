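#' Parameters of the allosteric enzyme-pair circuit
#'
#' A realistic one-dimensional implementation of the learning motif built from
#' a pair of self-activating allosteric enzymes. The active form of E+
#' catalyzes production of the metabolite x, the active form of E- catalyzes
#' its degradation, and x controls the self-catalytic branches through Hill
#' functions:
#' \deqn{\tau_x \dot x = \gamma_+ a_+ - \gamma_- x a_- - x D(t)}
#' \deqn{\tau_a \dot a_+ = a_+ \frac{c_+^n}{c_+^n + x^n} - a_+ \kappa_+}
#' \deqn{\tau_a \dot a_- = a_- \frac{x^m}{c_-^m + x^m} - a_- \kappa_-}
#'
#' Default rationale: the activating branch half-saturates below the set point
#' (`c_plus = 0.5`) and the repressing branch above it (`c_minus = 2`), so both
#' branch growth rates are convex in x at the set point and fluctuations of x
#' raise both time-averaged growth rates -- the variance-rectification that
#' drives learning. The decay rates equal the branch rates at x = 1
#' (`kappa = 0.2`), pinning the static fixed point at the set point exactly
#' with both branches marginal; the free overall scale of (a+, a-) is the
#' memory degree of freedom.
#'
#' @param gamma_plus,gamma_minus catalytic rates of production/degradation.
#' @param c_plus,c_minus Hill half-saturation constants (concentration).
#' @param n,m Hill exponents (>= 1).
#' @param kappa_plus,kappa_minus decay rates of the active enzyme forms.
#' @param tau_x,tau_a metabolite and enzyme timescales; `tau_x << tau_a`.
#' @return Object of class `allosteric_params`.
#' @export
allosteric_params <- function(gamma_plus = 1, gamma_minus = 1, c_plus = 0.5,
                              c_minus = 2, n = 2, m = 2, kappa_plus = 0.2,
                              kappa_minus = 0.2, tau_x = 0.01, tau_a = 10) {
  vals <- c(gamma_plus, gamma_minus, c_plus, c_minus, n, m, kappa_plus,
            kappa_minus, tau_x, tau_a)
  if (any(vals <= 0)) stop("all allosteric parameters must be positive")
  if (n < 1 || m < 1) stop("Hill exponents must be >= 1")
  if (tau_x >= tau_a) stop("need timescale separation tau_x < tau_a")
  structure(list(gamma_plus = gamma_plus, gamma_minus = gamma_minus,
                 c_plus = c_plus, c_minus = c_minus, n = n, m = m,
                 kappa_plus = kappa_plus, kappa_minus = kappa_minus,
                 tau_x = tau_x, tau_a = tau_a),
            class = "allosteric_params")
}

#' Simulate the allosteric enzyme-pair circuit
#'
#' Integrates the enzyme-pair dynamics (see [allosteric_params()]) driven by a
#' one-dimensional demand trajectory. The stiff metabolite equation is solved
#' in quasi-steady state, \eqn{x = \gamma_+ a_+ / (\gamma_- a_- + D)}, when
#' `tau_x/tau_a < qss_ratio`, and by sub-stepped explicit Euler otherwise.
#' With `learning = FALSE` the repressing branch is dropped, leaving the
#' single-activator end-product-inhibition analogue whose enzyme level is
#' enslaved to the mean demand and cannot store fluctuation information.
#'
#' @param demand a one-dimensional `demand_trajectory`.
#' @param params an [allosteric_params()].
#' @param learning keep the repressing branch (the learning circuit) or drop
#'   it (the non-learning analogue).
#' @param a0 initial activities `c(a_plus, a_minus)`.
#' @param discard fraction of each epoch discarded in the summaries.
#' @param record_every thinning of the stored trajectory.
#' @param qss_ratio timescale-ratio threshold for the quasi-steady-state
#'   treatment of x.
#' @return Object of class `biochem_trajectory` with stored `x`, `a_plus`,
#'   `a_minus` and per-epoch summaries (`mse_x`, the homeostatic error
#'   \eqn{\langle (x-1)^2 \rangle}; mean activities).
#' @export
simulate_allosteric <- function(demand, params = allosteric_params(),
                                learning = TRUE, a0 = c(1, 0.5),
                                discard = 0.3, record_every = 1L,
                                qss_ratio = 1e-2) {
  stopifnot(inherits(demand, "demand_trajectory"))
  if (ncol(demand$D) != 1) stop("the allosteric circuit is one-dimensional")
  res <- cpp_sim_allosteric(demand$D[, 1], demand$epoch, demand$dt,
                            params$gamma_plus, params$gamma_minus,
                            params$c_plus, params$c_minus, params$n, params$m,
                            params$kappa_plus, params$kappa_minus,
                            params$tau_x, params$tau_a, isTRUE(learning),
                            a0[1], a0[2], 1e-9, discard, qss_ratio,
                            as.integer(record_every))
  structure(list(times = demand$times[res$idx], x = res$traj[, 1],
                 a_plus = res$traj[, 2], a_minus = res$traj[, 3],
                 epoch = demand$epoch[res$idx],
                 epoch_stats = data.frame(epoch = seq_along(res$mse_x),
                                          mse_x = res$mse_x,
                                          mean_x = res$mean_x,
                                          mean_a_plus = res$mean_ap,
                                          mean_a_minus = res$mean_am),
                 params = params, learning = isTRUE(learning),
                 kind = "allosteric"),
            class = "biochem_trajectory")
}

#' Parameters of the bifunctional-enzyme homeostasis circuit
#'
#' A compact homeostasis circuit in which synthesis and degradation of x are
#' catalyzed by the same bifunctional enzyme E. With
#' \eqn{A = a_+ + a_- = [E] + [xE]} the total enzyme level, the bound and
#' unbound fractions follow the Hill partition
#' \eqn{a_+ = A c^m/(x^m + c^m)}, \eqn{a_- = A - a_+}, and
#' \deqn{\tau_x \dot x = P_0 + \gamma_+ a_+ - \gamma_- x a_- - x D(t)}
#' \deqn{\tau_A \dot A = -A\kappa + f(x), \qquad f(x) = \beta (x-1)^2 + f_0.}
#' The production-control function f is minimized at the set point, so
#' fluctuations of x upregulate the enzyme -- f acts as a variance sensor --
#' and the circuit's responsiveness scales with A. With the default
#' \eqn{c = 1} and \eqn{\gamma_+ = \gamma_-}, the production balance at
#' \eqn{x = 1} is independent of A and the basal production `P0` matches the
#' mean demand.
#'
#' @param P0 basal production (set equal to the mean demand).
#' @param gamma_plus,gamma_minus catalytic rates.
#' @param c Hill half-saturation of the enzyme-metabolite binding.
#' @param m Hill exponent.
#' @param kappa enzyme decay rate.
#' @param beta,f0 curvature and basal level of the production-control
#'   function f.
#' @param tau_x,tau_A metabolite and enzyme timescales.
#' @return Object of class `bifunctional_params`.
#' @export
bifunctional_params <- function(P0 = 1, gamma_plus = 1, gamma_minus = 1,
                                c = 1, m = 2, kappa = 0.01, beta = 1,
                                f0 = 1e-4, tau_x = 0.01, tau_A = 20) {
  vals <- c(P0, gamma_plus, gamma_minus, c, m, kappa, beta, f0, tau_x, tau_A)
  if (any(vals <= 0)) stop("all bifunctional parameters must be positive")
  if (tau_x >= tau_A) stop("need timescale separation tau_x < tau_A")
  structure(list(P0 = P0, gamma_plus = gamma_plus, gamma_minus = gamma_minus,
                 c = c, m = m, kappa = kappa, beta = beta, f0 = f0,
                 tau_x = tau_x, tau_A = tau_A),
            class = "bifunctional_params")
}

#' Simulate the bifunctional-enzyme homeostasis circuit
#'
#' Integrates the bifunctional-enzyme dynamics (see [bifunctional_params()]).
#' The stiff metabolite balance is monotone in x and is solved by Newton
#' iteration each step when `tau_x/tau_A < qss_ratio`. With
#' `learning = FALSE` the enzyme level A is frozen at its static-demand steady
#' state \eqn{f_0/\kappa}, the non-learning analogue.
#'
#' @inheritParams simulate_allosteric
#' @param params a [bifunctional_params()].
#' @param A0 initial total enzyme level; default is the static-demand steady
#'   state `f0 / kappa` (which is also the frozen level of the non-learning
#'   analogue).
#' @return Object of class `biochem_trajectory` with stored `x`, `A`, the
#'   Hill partition `a_plus`, `a_minus` (which satisfy
#'   `a_plus + a_minus == A` exactly), and per-epoch summaries.
#' @export
simulate_bifunctional <- function(demand, params = bifunctional_params(),
                                  learning = TRUE, discard = 0.3,
                                  record_every = 1L, qss_ratio = 1e-2,
                                  A0 = NULL) {
  stopifnot(inherits(demand, "demand_trajectory"))
  if (ncol(demand$D) != 1) stop("the bifunctional circuit is one-dimensional")
  if (is.null(A0)) A0 <- params$f0 / params$kappa
  res <- cpp_sim_bifunctional(demand$D[, 1], demand$epoch, demand$dt,
                              params$P0, params$gamma_plus,
                              params$gamma_minus, params$c, params$m,
                              params$kappa, params$beta, params$f0,
                              params$tau_x, params$tau_A, isTRUE(learning),
                              A0, discard, qss_ratio,
                              as.integer(record_every))
  x <- res$traj[, 1]
  A <- res$traj[, 2]
  a_plus <- A * params$c^params$m / (x^params$m + params$c^params$m)
  structure(list(times = demand$times[res$idx], x = x, A = A,
                 a_plus = a_plus, a_minus = A - a_plus,
                 epoch = demand$epoch[res$idx],
                 epoch_stats = data.frame(epoch = seq_along(res$mse_x),
                                          mse_x = res$mse_x,
                                          mean_x = res$mean_x,
                                          mean_A = res$mean_A),
                 params = params, learning = isTRUE(learning),
                 kind = "bifunctional"),
            class = "biochem_trajectory")
}

#' @export
print.biochem_trajectory <- function(x, ...) {
  cat(sprintf("Biochemical circuit trajectory (%s, learning %s)\n", x$kind,
              if (x$learning) "on" else "off"))
  print(x$epoch_stats, row.names = FALSE)
  invisible(x)
}
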