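#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler--Maruyama simulation of the epoch-structured OU demand process.
// One epoch per entry of gamma/n_steps; M_flat holds the Nx*Nx anisotropy
// matrix of each epoch (column-major, stacked). State carries over between
// epochs. Demands are floored at eps_floor component-wise and the number of
// floored points is counted. Uses R's RNG (norm_rand) so set.seed() governs.
// [[Rcpp::export]]
List cpp_sim_ou(NumericVector d_start, NumericVector dbar, NumericMatrix M_flat,
                NumericVector gamma, IntegerVector n_steps, double dt,
                double eps_floor) {
  const int nx = d_start.size();
  const int nep = gamma.size();
  long total = 0;
  for (int e = 0; e < nep; ++e) total += n_steps[e];

  NumericMatrix D(total, nx);
  IntegerVector epoch(total);
  std::vector<double> d(d_start.begin(), d_start.end());
  std::vector<double> drift(nx);
  long clamp = 0, row = 0;

  for (int e = 0; e < nep; ++e) {
    const double sg = std::sqrt(2.0 * gamma[e] * dt);
    for (int s = 0; s < n_steps[e]; ++s) {
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int j = 0; j < nx; ++j)
          acc += M_flat(i, e * nx + j) * (d[j] - dbar[j]);
        drift[i] = acc;
      }
      for (int i = 0; i < nx; ++i) {
        d[i] += -drift[i] * dt + sg * norm_rand();
        if (d[i] < eps_floor) { d[i] = eps_floor; ++clamp; }
        D(row, i) = d[i];
      }
      epoch[row] = e + 1;
      ++row;
    }
  }
  return List::create(_["D"] = D, _["epoch"] = epoch,
                      _["clamp_count"] = (double)clamp);
}

// Shared per-epoch accumulator for circuit simulations.
struct EpochAcc {
  int nep, nx, na;
  std::vector<long> start, len;
  std::vector<double> perf, cip, mean_x, mean_a, n_ret, n_cip;
  std::vector<double> prevP;
  bool havePrev;
  EpochAcc(const IntegerVector &epoch, int nep_, int nx_, int na_)
      : nep(nep_), nx(nx_), na(na_), start(nep_, -1), len(nep_, 0),
        perf(nep_, 0.0), cip(nep_, 0.0), mean_x(nep_ * nx_, 0.0),
        mean_a(nep_ * na_, 0.0), n_ret(nep_, 0.0), n_cip(nep_, 0.0),
        prevP(nx_, 0.0), havePrev(false) {
    for (long i = 0; i < epoch.size(); ++i) {
      int e = epoch[i] - 1;
      if (start[e] < 0) start[e] = i;
      ++len[e];
    }
  }
  // returns true when index i is in the retained (post-discard) part
  bool retained(long i, int e, double discard) const {
    return (i - start[e]) >= (long)std::ceil(discard * (double)len[e]);
  }
};

// Learning circuit of the excess-regulator architecture:
//   x_i = P_i / D_i,  P_i = sum_mu sigma[mu,i] a_mu,
//   tau_a da_mu/dt = pre * max(d, sum_i sigma[mu,i] (1 - x_i)) - kappa a_mu,
// with pre = a_mu (self-activation on) or 1 (off). Explicit Euler on the
// demand grid. Activities floored at a_floor when self-activation is on;
// productions floored at p_floor before the division (both counted).
// [[Rcpp::export]]
List cpp_sim_learning(NumericMatrix D, IntegerVector epoch, NumericMatrix sigma,
                      double dt, double tau_a, double kappa, double d_nl,
                      bool self_act, double a_floor, double p_floor,
                      NumericVector a0, double discard, int record_every) {
  const long n = D.nrow();
  const int nx = D.ncol(), na = sigma.nrow();
  const int nep = max(epoch);
  EpochAcc acc(epoch, nep, nx, na);

  std::vector<double> a(a0.begin(), a0.end());
  std::vector<double> P(nx), x(nx), drv(na);
  long nrec = (n + record_every - 1) / record_every;
  NumericMatrix a_rec(nrec, na), P_rec(nrec, nx), x_rec(nrec, nx);
  IntegerVector idx_rec(nrec);
  long a_hits = 0, p_hits = 0, rrow = 0;

  for (long t = 0; t < n; ++t) {
    const int e = epoch[t] - 1;
    for (int i = 0; i < nx; ++i) {
      double acc_p = 0.0;
      for (int m = 0; m < na; ++m) acc_p += sigma(m, i) * a[m];
      if (acc_p < p_floor) { acc_p = p_floor; ++p_hits; }
      P[i] = acc_p;
      x[i] = acc_p / D(t, i);
    }
    if (t % record_every == 0) {
      for (int m = 0; m < na; ++m) a_rec(rrow, m) = a[m];
      for (int i = 0; i < nx; ++i) { P_rec(rrow, i) = P[i]; x_rec(rrow, i) = x[i]; }
      idx_rec[rrow] = (int)(t + 1);
      ++rrow;
    }
    const bool ret = acc.retained(t, e, discard);
    if (ret) {
      double mis = 0.0;
      for (int i = 0; i < nx; ++i) {
        const double di = P[i] - D(t, i);
        mis += di * di;
        acc.mean_x[e * nx + i] += x[i];
      }
      acc.perf[e] -= mis;
      for (int m = 0; m < na; ++m) acc.mean_a[e * na + m] += a[m];
      acc.n_ret[e] += 1.0;
      if (acc.havePrev) {
        double pw = 0.0;
        for (int i = 0; i < nx; ++i) {
          const double dp = (P[i] - acc.prevP[i]) / dt;
          pw += dp * dp;
        }
        acc.cip[e] += pw;
        acc.n_cip[e] += 1.0;
      }
      for (int i = 0; i < nx; ++i) acc.prevP[i] = P[i];
      acc.havePrev = true;
    } else {
      acc.havePrev = false;
    }
    for (int m = 0; m < na; ++m) {
      double proj = 0.0;
      for (int i = 0; i < nx; ++i) proj += sigma(m, i) * (1.0 - x[i]);
      drv[m] = proj > d_nl ? proj : d_nl;
    }
    for (int m = 0; m < na; ++m) {
      const double pre = self_act ? a[m] : 1.0;
      a[m] += dt / tau_a * (pre * drv[m] - kappa * a[m]);
      if (self_act && a[m] < a_floor) { a[m] = a_floor; ++a_hits; }
    }
  }

  NumericVector perf(nep), cip(nep);
  NumericMatrix mean_a(nep, na), mean_x(nep, nx);
  for (int e = 0; e < nep; ++e) {
    perf[e] = acc.perf[e] / acc.n_ret[e];
    cip[e] = acc.n_cip[e] > 0 ? acc.cip[e] / acc.n_cip[e] : NA_REAL;
    for (int m = 0; m < na; ++m) mean_a(e, m) = acc.mean_a[e * na + m] / acc.n_ret[e];
    for (int i = 0; i < nx; ++i) mean_x(e, i) = acc.mean_x[e * nx + i] / acc.n_ret[e];
  }
  return List::create(_["idx"] = idx_rec, _["a"] = a_rec, _["P"] = P_rec,
                      _["x"] = x_rec, _["perf"] = perf, _["cip"] = cip,
                      _["mean_a"] = mean_a, _["mean_x"] = mean_x,
                      _["a_floor_hits"] = (double)a_hits,
                      _["p_floor_hits"] = (double)p_hits);
}

// Simple end-product inhibition, one regulator per metabolite:
//   x_i = P_i / D_i,  P_i = a_i,  tau_a da_i/dt = 1 - x_i.
// [[Rcpp::export]]
List cpp_sim_sepi(NumericMatrix D, IntegerVector epoch, double dt, double tau_a,
                  NumericVector a0, double p_floor, double discard,
                  int record_every) {
  const long n = D.nrow();
  const int nx = D.ncol();
  const int nep = max(epoch);
  EpochAcc acc(epoch, nep, nx, nx);

  std::vector<double> a(a0.begin(), a0.end());
  std::vector<double> P(nx), x(nx);
  long nrec = (n + record_every - 1) / record_every;
  NumericMatrix a_rec(nrec, nx), P_rec(nrec, nx), x_rec(nrec, nx);
  IntegerVector idx_rec(nrec);
  long p_hits = 0, rrow = 0;

  for (long t = 0; t < n; ++t) {
    const int e = epoch[t] - 1;
    for (int i = 0; i < nx; ++i) {
      double p = a[i];
      if (p < p_floor) { p = p_floor; ++p_hits; }
      P[i] = p;
      x[i] = p / D(t, i);
    }
    if (t % record_every == 0) {
      for (int i = 0; i < nx; ++i) {
        a_rec(rrow, i) = a[i]; P_rec(rrow, i) = P[i]; x_rec(rrow, i) = x[i];
      }
      idx_rec[rrow] = (int)(t + 1);
      ++rrow;
    }
    const bool ret = acc.retained(t, e, discard);
    if (ret) {
      double mis = 0.0;
      for (int i = 0; i < nx; ++i) {
        const double di = P[i] - D(t, i);
        mis += di * di;
        acc.mean_x[e * nx + i] += x[i];
        acc.mean_a[e * nx + i] += a[i];
      }
      acc.perf[e] -= mis;
      acc.n_ret[e] += 1.0;
      if (acc.havePrev) {
        double pw = 0.0;
        for (int i = 0; i < nx; ++i) {
          const double dp = (P[i] - acc.prevP[i]) / dt;
          pw += dp * dp;
        }
        acc.cip[e] += pw;
        acc.n_cip[e] += 1.0;
      }
      for (int i = 0; i < nx; ++i) acc.prevP[i] = P[i];
      acc.havePrev = true;
    } else {
      acc.havePrev = false;
    }
    for (int i = 0; i < nx; ++i) a[i] += dt / tau_a * (1.0 - x[i]);
  }

  NumericVector perf(nep), cip(nep);
  NumericMatrix mean_a(nep, nx), mean_x(nep, nx);
  for (int e = 0; e < nep; ++e) {
    perf[e] = acc.perf[e] / acc.n_ret[e];
    cip[e] = acc.n_cip[e] > 0 ? acc.cip[e] / acc.n_cip[e] : NA_REAL;
    for (int i = 0; i < nx; ++i) {
      mean_a(e, i) = acc.mean_a[e * nx + i] / acc.n_ret[e];
      mean_x(e, i) = acc.mean_x[e * nx + i] / acc.n_ret[e];
    }
  }
  return List::create(_["idx"] = idx_rec, _["a"] = a_rec, _["P"] = P_rec,
                      _["x"] = x_rec, _["perf"] = perf, _["cip"] = cip,
                      _["mean_a"] = mean_a, _["mean_x"] = mean_x,
                      _["p_floor_hits"] = (double)p_hits);
}

// Allosteric enzyme pair (1D homeostasis):
//   tau_x dx/dt = gp*ap - gm*x*am - x*D(t)
//   tau_a dap/dt = ap * cp^n/(cp^n + x^n) - ap*kp
//   tau_a dam/dt = am * x^m/(cm^m + x^m) - am*km
// learning = false drops the repressor branch (am == 0), the end-product
// inhibition analogue. x handled by quasi-steady state (closed form) when
// tau_x/tau_a < qss_ratio, else sub-stepped explicit Euler.
// [[Rcpp::export]]
List cpp_sim_allosteric(NumericVector D, IntegerVector epoch, double dt,
                        double gp, double gm, double cp, double cm, double hn,
                        double hm, double kp, double km, double tau_x,
                        double tau_a, bool learning, double ap0, double am0,
                        double a_floor, double discard, double qss_ratio,
                        int record_every) {
  const long n = D.size();
  const int nep = max(epoch);
  EpochAcc acc(epoch, nep, 1, 2);
  const bool qss = (tau_x / tau_a) < qss_ratio;
  const int nsub = qss ? 1 : std::max(1, (int)std::ceil(10.0 * dt / tau_x));

  double ap = ap0, am = learning ? am0 : 0.0;
  double x = gp * ap / (gm * am + D[0]);
  long nrec = (n + record_every - 1) / record_every;
  NumericMatrix traj(nrec, 3); // x, ap, am
  IntegerVector idx_rec(nrec);
  long rrow = 0;
  std::vector<double> mse(nep, 0.0);

  for (long t = 0; t < n; ++t) {
    const int e = epoch[t] - 1;
    if (qss) {
      x = gp * ap / (gm * am + D[t]);
    } else {
      const double h = dt / nsub;
      for (int s = 0; s < nsub; ++s)
        x += h / tau_x * (gp * ap - gm * x * am - x * D[t]);
      if (x < 0) x = 0;
    }
    if (t % record_every == 0) {
      traj(rrow, 0) = x; traj(rrow, 1) = ap; traj(rrow, 2) = am;
      idx_rec[rrow] = (int)(t + 1);
      ++rrow;
    }
    if (acc.retained(t, e, discard)) {
      const double dx = x - 1.0;
      mse[e] += dx * dx;
      acc.mean_x[e] += x;
      acc.mean_a[e * 2 + 0] += ap;
      acc.mean_a[e * 2 + 1] += am;
      acc.n_ret[e] += 1.0;
    }
    const double hp = std::pow(cp, hn) / (std::pow(cp, hn) + std::pow(x, hn));
    ap += dt / tau_a * ap * (hp - kp);
    if (ap < a_floor) ap = a_floor;
    if (learning) {
      const double hmv = std::pow(x, hm) / (std::pow(cm, hm) + std::pow(x, hm));
      am += dt / tau_a * am * (hmv - km);
      if (am < a_floor) am = a_floor;
    }
  }

  NumericVector mse_x(nep), mean_x(nep), mean_ap(nep), mean_am(nep);
  for (int e = 0; e < nep; ++e) {
    mse_x[e] = mse[e] / acc.n_ret[e];
    mean_x[e] = acc.mean_x[e] / acc.n_ret[e];
    mean_ap[e] = acc.mean_a[e * 2 + 0] / acc.n_ret[e];
    mean_am[e] = acc.mean_a[e * 2 + 1] / acc.n_ret[e];
  }
  return List::create(_["idx"] = idx_rec, _["traj"] = traj, _["mse_x"] = mse_x,
                      _["mean_x"] = mean_x, _["mean_ap"] = mean_ap,
                      _["mean_am"] = mean_am);
}

// Bifunctional-enzyme homeostasis circuit:
//   a+ = A c^m/(x^m + c^m), a- = A - a+           (Hill partition)
//   tau_x dx/dt = P0 + gp*a+ - gm*x*a- - x*D(t)
//   tau_A dA/dt = -A*kappa + f(x),  f(x) = beta (x - 1)^2 + f0
// learning = false freezes A at its static-demand steady state f0/kappa.
// Quasi-steady x solved by damped Newton (the balance is monotone in x).
// [[Rcpp::export]]
List cpp_sim_bifunctional(NumericVector D, IntegerVector epoch, double dt,
                          double P0, double gp, double gm, double cc, double hm,
                          double kappa, double beta, double f0, double tau_x,
                          double tau_A, bool learning, double A0,
                          double discard, double qss_ratio, int record_every) {
  const long n = D.size();
  const int nep = max(epoch);
  EpochAcc acc(epoch, nep, 1, 1);
  const bool qss = (tau_x / tau_A) < qss_ratio;
  const int nsub = qss ? 1 : std::max(1, (int)std::ceil(10.0 * dt / tau_x));
  const double cm = std::pow(cc, hm);

  double A = A0;
  double x = 1.0;
  long nrec = (n + record_every - 1) / record_every;
  NumericMatrix traj(nrec, 2); // x, A
  IntegerVector idx_rec(nrec);
  long rrow = 0;
  std::vector<double> mse(nep, 0.0);

  for (long t = 0; t < n; ++t) {
    const int e = epoch[t] - 1;
    if (qss) {
      // Newton on g(x) = P0 + gp*A*hb - gm*x*A*(1-hb) - x*D, hb = c^m/(c^m+x^m)
      for (int it = 0; it < 60; ++it) {
        const double xm = std::pow(x, hm);
        const double hb = cm / (cm + xm);
        const double dhb = -hm * std::pow(x, hm - 1.0) * cm / ((cm + xm) * (cm + xm));
        const double g = P0 + gp * A * hb - gm * x * A * (1.0 - hb) - x * D[t];
        const double dg = gp * A * dhb - gm * A * ((1.0 - hb) - x * dhb) - D[t];
        double step = g / dg;
        x -= step;
        if (x < 1e-9) x = 1e-9;
        if (std::fabs(step) < 1e-12) break;
      }
    } else {
      const double h = dt / nsub;
      for (int s = 0; s < nsub; ++s) {
        const double xm = std::pow(x, hm);
        const double hb = cm / (cm + xm);
        x += h / tau_x * (P0 + gp * A * hb - gm * x * A * (1.0 - hb) - x * D[t]);
        if (x < 1e-9) x = 1e-9;
      }
    }
    if (t % record_every == 0) {
      traj(rrow, 0) = x; traj(rrow, 1) = A;
      idx_rec[rrow] = (int)(t + 1);
      ++rrow;
    }
    if (acc.retained(t, e, discard)) {
      const double dx = x - 1.0;
      mse[e] += dx * dx;
      acc.mean_x[e] += x;
      acc.mean_a[e] += A;
      acc.n_ret[e] += 1.0;
    }
    if (learning) {
      const double dx = x - 1.0;
      A += dt / tau_A * (-A * kappa + beta * dx * dx + f0);
      if (A < 0) A = 0;
    }
  }

  NumericVector mse_x(nep), mean_x(nep), mean_A(nep);
  for (int e = 0; e < nep; ++e) {
    mse_x[e] = mse[e] / acc.n_ret[e];
    mean_x[e] = acc.mean_x[e] / acc.n_ret[e];
    mean_A[e] = acc.mean_a[e] / acc.n_ret[e];
  }
  return List::create(_["idx"] = idx_rec, _["traj"] = traj, _["mse_x"] = mse_x,
                      _["mean_x"] = mean_x, _["mean_A"] = mean_A);
}
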