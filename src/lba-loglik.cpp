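// Hot-path likelihood kernels for the hierarchical sampler: per-trial log
// defective densities and the chance-level mixture for deadline-censored
// trials. Semantics mirror the R reference implementations built on
// lba_pdf()/lba_cdf(); densities are floored at 1e-300 before logging and
// structural violations (decision time <= 0) return -Inf.
#include <Rcpp.h>
using namespace Rcpp;

static inline double lba_f(double t, double ts, double A, double b, double v,
                           double s) {
  double z1 = (b - A - t * v) / ts, z2 = (b - t * v) / ts;
  double f = (-v * R::pnorm(z1, 0, 1, 1, 0) + s * R::dnorm(z1, 0, 1, 0) +
               v * R::pnorm(z2, 0, 1, 1, 0) - s * R::dnorm(z2, 0, 1, 0)) / A;
  return f > 0 ? f : 0;
}

static inline double lba_surv(double t, double ts, double A, double b,
                              double v, double s) {
  double z1 = (b - A - t * v) / ts, z2 = (b - t * v) / ts;
  double F = 1.0 + ((b - A - t * v) / A) * R::pnorm(z1, 0, 1, 1, 0) -
             ((b - t * v) / A) * R::pnorm(z2, 0, 1, 1, 0) +
             (ts / A) * (R::dnorm(z1, 0, 1, 0) - R::dnorm(z2, 0, 1, 0));
  double S = 1.0 - F;
  if (S < 0) S = 0;
  if (S > 1) S = 1;
  return S;
}

// [[Rcpp::export(name = ".cpp_log_defective")]]
NumericVector cpp_log_defective(NumericVector td, NumericVector A,
                                NumericVector b, NumericVector vw,
                                NumericVector vl, double s) {
  R_xlen_t n = td.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double t = td[i];
    if (!R_finite(t) || t <= 0) { out[i] = R_NegInf; continue; }
    double ts = t * s;
    double dens = lba_f(t, ts, A[i], b[i], vw[i], s) *
                  lba_surv(t, ts, A[i], b[i], vl[i], s);
    out[i] = log(dens > 1e-300 ? dens : 1e-300);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_log_missing_mix")]]
NumericVector cpp_log_missing_mix(NumericVector tau, NumericVector A,
                                  NumericVector b, NumericVector vc,
                                  NumericVector vi, NumericVector t0,
                                  double s) {
  R_xlen_t n = tau.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double t = tau[i] - t0[i];
    if (!R_finite(t) || t <= 0) { out[i] = R_NegInf; continue; }
    double ts = t * s;
    double fc = lba_f(t, ts, A[i], b[i], vc[i], s);
    double fi = lba_f(t, ts, A[i], b[i], vi[i], s);
    double Sc = lba_surv(t, ts, A[i], b[i], vc[i], s);
    double Si = lba_surv(t, ts, A[i], b[i], vi[i], s);
    double dens = 0.5 * fc * Si + 0.5 * fi * Sc;
    out[i] = log(dens > 1e-300 ? dens : 1e-300);
  }
  return out;
}

// Whole-trial evaluators: do the per-trial parameter lookup in C++ too.
// theta is the n_participants x 15 matrix (12 drifts natural scale, then
// logA, logk, logt0); pid is 1-based participant index per trial; cw/cl are
// 1-based winner/loser drift columns.

// [[Rcpp::export(name = ".cpp_eval_obs")]]
NumericVector cpp_eval_obs(NumericMatrix theta, IntegerVector pid,
                           IntegerVector cw, IntegerVector cl,
                           NumericVector rt, double s) {
  int np = theta.nrow();
  std::vector<double> Ae(np), be(np), t0e(np);
  for (int p = 0; p < np; ++p) {
    Ae[p] = exp(theta(p, 12));
    be[p] = Ae[p] + exp(theta(p, 13));
    t0e[p] = exp(theta(p, 14));
  }
  R_xlen_t n = pid.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int p = pid[i] - 1;
    double t = rt[i] - t0e[p];
    if (!R_finite(t) || t <= 0) { out[i] = R_NegInf; continue; }
    double ts = t * s;
    double dens = lba_f(t, ts, Ae[p], be[p], theta(p, cw[i] - 1), s) *
                  lba_surv(t, ts, Ae[p], be[p], theta(p, cl[i] - 1), s);
    out[i] = log(dens > 1e-300 ? dens : 1e-300);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_eval_mis")]]
NumericVector cpp_eval_mis(NumericMatrix theta, IntegerVector pid,
                           IntegerVector cc, IntegerVector ci,
                           NumericVector tau, double s) {
  int np = theta.nrow();
  std::vector<double> Ae(np), be(np), t0e(np);
  for (int p = 0; p < np; ++p) {
    Ae[p] = exp(theta(p, 12));
    be[p] = Ae[p] + exp(theta(p, 13));
    t0e[p] = exp(theta(p, 14));
  }
  R_xlen_t n = pid.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int p = pid[i] - 1;
    double t = tau[i] - t0e[p];
    if (!R_finite(t) || t <= 0) { out[i] = R_NegInf; continue; }
    double ts = t * s;
    double vc = theta(p, cc[i] - 1), vi = theta(p, ci[i] - 1);
    double dens = 0.5 * lba_f(t, ts, Ae[p], be[p], vc, s) *
                        lba_surv(t, ts, Ae[p], be[p], vi, s) +
                  0.5 * lba_f(t, ts, Ae[p], be[p], vi, s) *
                        lba_surv(t, ts, Ae[p], be[p], vc, s);
    out[i] = log(dens > 1e-300 ? dens : 1e-300);
  }
  return out;
}
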