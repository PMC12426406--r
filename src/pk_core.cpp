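// Compiled core for the semi-mechanistic busulfan model.
//
// States: y[0] = A1 central amount (mg), y[1] = A2 peripheral amount (mg),
//         y[2] = G  normalised GSH pool (dimensionless, starts at 1),
//         y[3] = running AUC of the central concentration (mg*h/L).
//
// Within any interval where the infusion rate and the occasion (IOV)
// multiplier on CL are constant the system is smooth; integration steps
// exactly to every discontinuity, so the adaptive Dormand-Prince 5(4)
// pair never straddles a kink.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct PkPar {
  double cl;    // L/h, subject-level (eta applied, kappa applied per segment)
  double vc;    // L
  double q;     // L/h
  double vp;    // L
  double sgsh;  // h/mg, subject-level depletion scale
  double kgsh;  // 1/h, GSH turnover
};

static inline void pk_rhs_c(const double* y, double* dy, const PkPar& p,
                            double rate, double clmult) {
  const double cl = p.cl * clmult;
  const double k10 = cl / p.vc;
  const double elim = k10 * y[2] * y[0];          // GSH-modulated elimination
  const double d12 = (p.q / p.vc) * y[0];
  const double d21 = (p.q / p.vp) * y[1];
  dy[0] = rate - elim - d12 + d21;
  dy[1] = d12 - d21;
  dy[2] = p.kgsh * (1.0 - y[2]) - (p.sgsh / p.vc) * elim;
  dy[3] = y[0] / p.vc;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// advance y from t0 to t1 with constant (rate, clmult); adaptive DP45
static void advance(double* y, double t0, double t1, const PkPar& p,
                    double rate, double clmult, double rtol, double atol) {
  if (t1 <= t0) return;
  const int n = 4;
  double t = t0;
  double h = std::min(t1 - t0, 0.25);
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4];
  double ytmp[4], ynew[4];
  pk_rhs_c(y, k1, p, rate, clmult);
  int iter = 0;
  while (t < t1) {
    if (++iter > 100000) stop("ODE integration failed: step count exceeded");
    if (h > t1 - t) h = t1 - t;
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    pk_rhs_c(ytmp, k2, p, rate, clmult);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    pk_rhs_c(ytmp, k3, p, rate, clmult);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    pk_rhs_c(ytmp, k4, p, rate, clmult);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    pk_rhs_c(ytmp, k5, p, rate, clmult);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    pk_rhs_c(ytmp, k6, p, rate, clmult);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    pk_rhs_c(ynew, k7, p, rate, clmult);
    // error estimate
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / n);
    if (!std::isfinite(errnorm)) stop("ODE integration failed: non-finite state");
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) { y[i] = ynew[i]; k1[i] = k7[i]; } // FSAL
      double fac = (errnorm > 0) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
    }
    if (h < 1e-12) stop("ODE integration failed: step size underflow");
  }
}

struct Schedule {
  std::vector<double> brk;     // interval boundaries, starting at 0
  std::vector<double> rate;    // infusion rate per interval
  std::vector<double> clmult;  // CL multiplier per interval
};

// Build piecewise-constant schedule from dose events and occasion windows.
static Schedule build_schedule(const NumericVector& d_start,
                               const NumericVector& d_dur,
                               const NumericVector& d_amt,
                               const NumericVector& occ_brk,
                               const NumericVector& occ_mult,
                               double tmax) {
  std::vector<double> pts;
  pts.push_back(0.0);
  pts.push_back(tmax);
  for (int i = 0; i < d_start.size(); ++i) {
    pts.push_back(d_start[i]);
    pts.push_back(d_start[i] + d_dur[i]);
  }
  for (int i = 0; i < occ_brk.size(); ++i) pts.push_back(occ_brk[i]);
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end(),
                        [](double a, double b) { return std::fabs(a - b) < 1e-12; }),
            pts.end());
  // clip to [0, tmax]
  std::vector<double> brk;
  for (double t : pts) if (t >= 0.0 && t <= tmax) brk.push_back(t);
  Schedule s;
  s.brk = brk;
  for (size_t j = 0; j + 1 < brk.size(); ++j) {
    double tm = 0.5 * (brk[j] + brk[j + 1]);
    double r = 0.0;
    for (int i = 0; i < d_start.size(); ++i)
      if (tm > d_start[i] && tm < d_start[i] + d_dur[i] && d_dur[i] > 0)
        r += d_amt[i] / d_dur[i];
    int occ = 0;
    for (int i = 0; i < occ_brk.size(); ++i) if (tm > occ_brk[i]) occ = i + 1;
    s.rate.push_back(r);
    s.clmult.push_back(occ_mult.size() > 0 ? occ_mult[occ] : 1.0);
  }
  return s;
}

// Simulate the state trajectory at sorted output times.
// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericVector d_start, NumericVector d_dur,
                           NumericVector d_amt, double cl, double vc,
                           double q, double vp, double sgsh, double kgsh,
                           NumericVector occ_brk, NumericVector occ_mult,
                           NumericVector out_times, double rtol, double atol) {
  const int m = out_times.size();
  double tmax = 0.0;
  for (int i = 0; i < m; ++i) tmax = std::max(tmax, out_times[i]);
  for (int i = 0; i < d_start.size(); ++i)
    tmax = std::max(tmax, d_start[i] + d_dur[i]);
  PkPar p{cl, vc, q, vp, sgsh, kgsh};
  Schedule s = build_schedule(d_start, d_dur, d_amt, occ_brk, occ_mult, tmax);
  double y[4] = {0.0, 0.0, 1.0, 0.0};
  NumericMatrix out(m, 4);
  int io = 0;
  while (io < m && out_times[io] <= 0.0) {
    for (int k = 0; k < 4; ++k) out(io, k) = y[k];
    ++io;
  }
  double t = 0.0;
  for (size_t j = 0; j + 1 < s.brk.size(); ++j) {
    double t1 = s.brk[j + 1];
    // outputs inside this interval
    while (io < m && out_times[io] <= t1 + 1e-12) {
      double tt = std::min(out_times[io], t1);
      advance(y, t, tt, p, s.rate[j], s.clmult[j], rtol, atol);
      t = tt;
      for (int k = 0; k < 4; ++k) out(io, k) = y[k];
      ++io;
    }
    advance(y, t, t1, p, s.rate[j], s.clmult[j], rtol, atol);
    t = t1;
  }
  for (; io < m; ++io)  // out times beyond tmax (shouldn't happen)
    for (int k = 0; k < 4; ++k) out(io, k) = y[k];
  return out;
}

// Exposure metrics for one replicate: integrate over the regimen and return
// cAUC at the horizon plus the running Cmax over a dense internal grid
// (<= 0.05 h during each infusion and the hour after; 0.25 h elsewhere).
// [[Rcpp::export]]
NumericVector cpp_profile_metrics(NumericVector d_start, NumericVector d_dur,
                                  NumericVector d_amt, double cl, double vc,
                                  double q, double vp, double sgsh,
                                  double kgsh, NumericVector occ_brk,
                                  NumericVector occ_mult, double horizon,
                                  double rtol, double atol,
                                  double cmax_tmax) {
  PkPar p{cl, vc, q, vp, sgsh, kgsh};
  Schedule s = build_schedule(d_start, d_dur, d_amt, occ_brk, occ_mult,
                              horizon);
  double y[4] = {0.0, 0.0, 1.0, 0.0};
  double cmax = 0.0, gmin = 1.0, cmax_w = 0.0;
  double t = 0.0;
  for (size_t j = 0; j + 1 < s.brk.size(); ++j) {
    double t1 = s.brk[j + 1];
    // dense sampling during/after infusions for the peak
    bool dense = false;
    double tm = 0.5 * (t + t1);
    for (int i = 0; i < d_start.size(); ++i)
      if (tm > d_start[i] && tm < d_start[i] + d_dur[i] + 1.0) dense = true;
    double step = dense ? 0.05 : 0.25;
    double tt = t;
    while (tt < t1 - 1e-12) {
      double tn = std::min(tt + step, t1);
      advance(y, tt, tn, p, s.rate[j], s.clmult[j], rtol, atol);
      tt = tn;
      double c = y[0] / p.vc;
      if (c > cmax) cmax = c;
      if (c > cmax_w && tt <= cmax_tmax) cmax_w = c;
      if (y[2] < gmin) gmin = y[2];
    }
    t = t1;
  }
  return NumericVector::create(y[3], cmax, gmin, cmax_w);
}

// -2 log joint density of one subject's observations and random effects,
// evaluated at random-effect vector b = (active etas..., kappas...).
// eta_idx: 0-based indices into b for (cl, vc, vp), or -1 if that eta is off.
// kap_off: 0-based index where per-occasion kappas start in b (-1 = no IOV).
// omega2: prior variances aligned with b.
// [[Rcpp::export]]
double cpp_subject_neg2ll(NumericVector b, NumericVector obs_times,
                          NumericVector dv, NumericVector d_start,
                          NumericVector d_dur, NumericVector d_amt,
                          double cl_base, double vc_base, double q_base,
                          double vp_base, double sgsh, double kgsh,
                          IntegerVector eta_idx, int kap_off,
                          NumericVector occ_brk, NumericVector omega2,
                          double sigma_prop, double sigma_add,
                          double rtol, double atol) {
  const double TWOPI = 6.283185307179586;
  double cl = cl_base, vc = vc_base, vp = vp_base;
  if (eta_idx[0] >= 0) cl *= std::exp(b[eta_idx[0]]);
  if (eta_idx[1] >= 0) vc *= std::exp(b[eta_idx[1]]);
  if (eta_idx[2] >= 0) vp *= std::exp(b[eta_idx[2]]);
  int n_occ = occ_brk.size() + 1;
  NumericVector occ_mult(n_occ, 1.0);
  if (kap_off >= 0)
    for (int k = 0; k < n_occ; ++k) occ_mult[k] = std::exp(b[kap_off + k]);
  NumericMatrix st = cpp_simulate(d_start, d_dur, d_amt, cl, vc, q_base, vp,
                                  sgsh, kgsh, occ_brk, occ_mult, obs_times,
                                  rtol, atol);
  double g = 0.0;
  for (int i = 0; i < obs_times.size(); ++i) {
    double f = st(i, 0) / vc;
    double v = f * sigma_prop * f * sigma_prop + sigma_add * sigma_add;
    double r = dv[i] - f;
    g += std::log(TWOPI * v) + r * r / v;
  }
  for (int i = 0; i < b.size(); ++i) {
    if (omega2[i] <= 0) {
      if (std::fabs(b[i]) > 1e-12) return R_PosInf;
      continue;
    }
    g += std::log(TWOPI * omega2[i]) + b[i] * b[i] / omega2[i];
  }
  return g;
}

// Model predictions (concentrations) at the observation times for a given b.
// [[Rcpp::export]]
NumericVector cpp_subject_pred(NumericVector b, NumericVector obs_times,
                               NumericVector d_start, NumericVector d_dur,
                               NumericVector d_amt, double cl_base,
                               double vc_base, double q_base, double vp_base,
                               double sgsh, double kgsh, IntegerVector eta_idx,
                               int kap_off, NumericVector occ_brk,
                               double rtol, double atol) {
  double cl = cl_base, vc = vc_base, vp = vp_base;
  if (eta_idx[0] >= 0) cl *= std::exp(b[eta_idx[0]]);
  if (eta_idx[1] >= 0) vc *= std::exp(b[eta_idx[1]]);
  if (eta_idx[2] >= 0) vp *= std::exp(b[eta_idx[2]]);
  int n_occ = occ_brk.size() + 1;
  NumericVector occ_mult(n_occ, 1.0);
  if (kap_off >= 0)
    for (int k = 0; k < n_occ; ++k) occ_mult[k] = std::exp(b[kap_off + k]);
  NumericMatrix st = cpp_simulate(d_start, d_dur, d_amt, cl, vc, q_base, vp,
                                  sgsh, kgsh, occ_brk, occ_mult, obs_times,
                                  rtol, atol);
  NumericVector f(obs_times.size());
  for (int i = 0; i < obs_times.size(); ++i) f[i] = st(i, 0) / vc;
  return f;
}
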