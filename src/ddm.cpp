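// Wiener first-passage-time density, trial simulator, and the
// regression log-likelihood used by the hierarchical sampler.
//
// Density follows the small-time / large-time series decomposition with an
// adaptive switch chosen per evaluation so that the truncation error of the
// standardized density is below WFPT_EPS.

#include <Rcpp.h>
using namespace Rcpp;

static const double WFPT_EPS = 1e-10;  // truncation error in f(tt|0,1,w) units
static const double PI_ = 3.14159265358979323846;

// standardized density of absorption at the LOWER bound at scaled time tt,
// unit boundary separation, relative start w, zero drift
static double fw_std(double tt, double w) {
  if (tt <= 0) return 0.0;
  // number of terms needed (Navarro-Fuss style bounds)
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * PI_ * tt) * WFPT_EPS < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * WFPT_EPS * std::sqrt(2.0 * PI_ * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (PI_ * tt * WFPT_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(PI_ * tt * WFPT_EPS) / (PI_ * PI_ * tt));
    kl = std::max(kl, 1.0 / (PI_ * std::sqrt(tt)));
  } else {
    kl = 1.0 / (PI_ * std::sqrt(tt));
  }
  double p = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    for (int k = -((K - 1) / 2); k <= ((K - 1) / 2) + 1; k++) {
      double u = w + 2.0 * k;
      p += u * std::exp(-u * u / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * PI_ * tt * tt * tt);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      p += k * std::exp(-k * k * PI_ * PI_ * tt / 2.0) * std::sin(k * PI_ * w);
    }
    p *= PI_;
  }
  return p;
}

// log density of first passage at the lower boundary at decision time td,
// threshold a, drift v, relative start z (from the lower boundary)
static double wfpt_lower_logd(double td, double a, double v, double z) {
  if (td <= 0 || a <= 0 || z <= 0 || z >= 1) return R_NegInf;
  double tt = td / (a * a);
  double p = fw_std(tt, z);
  if (p <= 0) return R_NegInf;
  return std::log(p) - v * a * z - v * v * td / 2.0 - 2.0 * std::log(a);
}

static double wfpt_logd(double t, bool upper, double a, double v, double z,
                        double t0) {
  double td = t - t0;
  if (td <= 0) return R_NegInf;
  if (upper) return wfpt_lower_logd(td, a, -v, 1.0 - z);
  return wfpt_lower_logd(td, a, v, z);
}

// [[Rcpp::export(name = ".wfpt_logpdf_cpp")]]
NumericVector wfpt_logpdf_cpp(NumericVector t, LogicalVector upper, double a,
                              double v, double z, double t0) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    bool up = (upper.size() == n) ? (bool)upper[i] : (bool)upper[0];
    out[i] = wfpt_logd(t[i], up, a, v, z, t0);
  }
  return out;
}

// Regression log-likelihood for one subject's revised decisions.
// pars = (a, t0, v0, v_stim, v_personal, v_social, z0, z_personal, z_social)
// Mixture with a uniform contaminant: (1-p_out) * WFPT + p_out * cont_dens,
// cont_dens already includes the half-mass-per-boundary factor.
// [[Rcpp::export(name = ".ddm_reg_loglik_cpp")]]
double ddm_reg_loglik_cpp(NumericVector rt, IntegerVector choice,
                          NumericVector stim, NumericVector pers,
                          NumericVector soc, NumericVector pars,
                          double p_outlier, double cont_dens) {
  double a = pars[0], t0 = pars[1];
  if (a <= 0 || t0 < 0) return R_NegInf;
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    double v = pars[2] + pars[3] * stim[i] + pars[4] * pers[i] + pars[5] * soc[i];
    double lp = pars[6] + pars[7] * pers[i] + pars[8] * soc[i];
    double z = 1.0 / (1.0 + std::exp(-lp));
    double ld = wfpt_logd(rt[i], choice[i] > 0, a, v, z, t0);
    double dens;
    if (ld == R_NegInf) {
      dens = p_outlier * cont_dens;
    } else {
      dens = (1.0 - p_outlier) * std::exp(ld) + p_outlier * cont_dens;
    }
    if (dens <= 0) return R_NegInf;
    ll += std::log(dens);
  }
  return ll;
}

// Euler-Maruyama path simulation; noise coefficient 1. A Brownian-bridge
// crossing test between step endpoints removes the O(sqrt(dt)) boundary
// overshoot bias of the plain Euler scheme. Paths not absorbed by tmax are
// resampled (count returned as attribute). Uses R's RNG.
// [[Rcpp::export(name = ".ddm_simulate_cpp")]]
NumericMatrix ddm_simulate_cpp(int n, double a, NumericVector v,
                               NumericVector z, double t0, double dt,
                               double tmax) {
  NumericMatrix out(n, 2);  // choice (+1 upper / -1 lower), rt
  RNGScope scope;
  double sdt = std::sqrt(dt);
  int resampled = 0;
  for (int i = 0; i < n; i++) {
    double vi = (v.size() == n) ? v[i] : v[0];
    double zi = (z.size() == n) ? z[i] : z[0];
    bool done = false;
    double t = 0.0;
    int ch = 0;
    while (!done) {
      double x = zi * a;
      t = 0.0;
      while (t < tmax) {
        double x_new = x + vi * dt + sdt * norm_rand();
        t += dt;
        if (x_new >= a) { ch = 1; done = true; break; }
        if (x_new <= 0) { ch = -1; done = true; break; }
        // bridge probability of an unobserved within-step crossing
        double p_up = std::exp(-2.0 * (a - x) * (a - x_new) / dt);
        double p_lo = std::exp(-2.0 * x * x_new / dt);
        if (p_up + p_lo > 1e-12) {
          double u = unif_rand();
          if (u < p_up) { ch = 1; done = true; break; }
          if (u < p_up + p_lo) { ch = -1; done = true; break; }
        }
        x = x_new;
      }
      if (!done) resampled++;
    }
    out(i, 0) = ch;
    out(i, 1) = t + t0;
  }
  out.attr("resampled") = resampled;
  return out;
}
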