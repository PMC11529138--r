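#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time density, unit diffusion coefficient.
// Strategy: express the density at the LOWER boundary of a process with
// drift v, boundary separation a and relative start w = z/a through the
// standardised density f(u | w) for a = 1, v = 0, u = (t - t0) / a^2, then
//   f_lower(t) = f(u | w) / a^2 * exp(-v a w - v^2 (t - t0) / 2).
// The upper-boundary density is f_lower with (v, w) -> (-v, 1 - w).
// f(u | w) has a small-time and a large-time series representation; the
// cheaper of the two (fewer terms for truncation error <= eps) is used.

static const double WFPT_EPS = 1e-7;

static double wfpt_std_logdensity(double u, double w) {
  // number of terms needed in each representation
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * WFPT_EPS < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * WFPT_EPS * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * WFPT_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * WFPT_EPS) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  // both branches are evaluated in log space (signed log-sum-exp) so the
  // density stays usable far into the tails, where the leading term alone
  // underflows a double
  if (ks < kl) {                       // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    double emax = R_NegInf;
    for (int k = lo; k <= hi; ++k) {
      double wk = w + 2.0 * k;
      double e = -wk * wk / (2.0 * u);
      if (e > emax) emax = e;
    }
    if (emax == R_NegInf) return R_NegInf;
    double s = 0.0;
    for (int k = lo; k <= hi; ++k) {
      double wk = w + 2.0 * k;
      s += wk * std::exp(-wk * wk / (2.0 * u) - emax);
    }
    if (s <= 0.0) return R_NegInf;
    return emax + std::log(s) -
      0.5 * std::log(2.0 * M_PI * u * u * u);
  } else {                             // large-time expansion
    int K = (int)std::ceil(kl);
    double emax = -M_PI * M_PI * u / 2.0;
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * std::exp(-k * k * M_PI * M_PI * u / 2.0 - emax) *
        std::sin(k * M_PI * w);
    }
    if (s <= 0.0) return R_NegInf;
    return emax + std::log(s) + std::log(M_PI);
  }
}

static double wfpt_logd(double rt, double a, double v, double t0, bool upper) {
  double t = rt - t0;
  if (!(t > 0.0)) return R_NegInf;
  double w = 0.5, vv = v;
  if (upper) { vv = -v; }              // w stays 0.5 for an unbiased start
  double u = t / (a * a);
  double lf = wfpt_std_logdensity(u, w);
  if (lf == R_NegInf) return R_NegInf;
  return lf - 2.0 * std::log(a) - vv * a * w - vv * vv * t / 2.0;
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_logd_cpp")]]
NumericVector wfpt_logd_cpp(NumericVector rt, double a, double v, double t0,
                            LogicalVector upper) {
  if (!(a > 0.0) || !R_finite(a) || !R_finite(v) || !R_finite(t0))
    stop("wfpt parameters must be finite with a > 0");
  R_xlen_t n = rt.size();
  if (upper.size() != n && upper.size() != 1)
    stop("'upper' must have length 1 or length(rt)");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    bool up = upper[upper.size() == 1 ? 0 : i];
    out[i] = wfpt_logd(rt[i], a, v, t0, up);
  }
  return out;
}

// Euler-Maruyama simulation of the diffusion from start a/2 to absorption,
// with the exact Brownian-bridge probability of an unobserved within-step
// boundary crossing, which removes the O(sqrt(dt)) discretisation bias of
// naive Euler absorption checks.
// [[Rcpp::export(name = ".fp_sim_cpp")]]
List fp_sim_cpp(int n, double a, double v, double t0, double dt,
                double max_t) {
  if (!(a > 0.0)) stop("boundary separation must be positive");
  if (!(dt > 0.0)) stop("dt must be positive");
  NumericVector rt(n);
  LogicalVector upper(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = a / 2.0, t = 0.0;
    bool up = false; bool done = false;
    while (!done) {
      double x1 = x + v * dt + sdt * norm_rand();
      t += dt;
      if (x1 >= a) { up = true; done = true; }
      else if (x1 <= 0.0) { up = false; done = true; }
      else {
        // bridge crossing probabilities within the step; the exp calls are
        // skipped when the exponent is below -30 (prob < 1e-13)
        double eu = -2.0 * (a - x) * (a - x1) / dt;
        double el = -2.0 * x * x1 / dt;
        if (eu > -30.0 || el > -30.0) {
          double pu = eu > -30.0 ? std::exp(eu) : 0.0;
          double pl = el > -30.0 ? std::exp(el) : 0.0;
          double uu = unif_rand();
          if (uu < pu) { up = true; done = true; }
          else if (uu < pu + pl) { up = false; done = true; }
        }
      }
      if (t > max_t && !done) {        // pathological drift/boundary inputs
        up = x1 > a / 2.0; done = true;
      }
      x = x1;
    }
    rt[i] = t + t0;
    upper[i] = up;
  }
  return List::create(_["rt"] = rt, _["upper"] = upper);
}

// Joint log-likelihood of one subject's trial sequence under the RL-DDM:
// runs the delta rule over the observed (choice, feedback) sequence, maps
// Q-value differences to trial drift rates, and accumulates the wfpt
// log-density of each (boundary, rt) with a uniform outlier contaminant.
// Response coding: upper boundary = the pair's optimal symbol.
// [[Rcpp::export(name = ".subject_loglik_cpp")]]
double subject_loglik_cpp(IntegerVector chosen, IntegerVector better,
                          IntegerVector worse, LogicalVector chose_opt,
                          NumericVector feedback, NumericVector rt,
                          int n_symbols,
                          double eta_pos, double eta_neg,
                          double v_scaling, double a, double t0,
                          double p_out, double unif_dens) {
  if (!(a > 0.0)) return R_NegInf;
  R_xlen_t n = rt.size();
  std::vector<double> q(n_symbols, 0.5);
  double ll = 0.0;
  double log_keep = std::log1p(-p_out);
  for (R_xlen_t i = 0; i < n; ++i) {
    double vq = (q[better[i]] - q[worse[i]]) * v_scaling;
    double ld = wfpt_logd(rt[i], a, vq, t0, chose_opt[i]);
    double dens;
    if (p_out > 0.0) {
      dens = std::exp(log_keep + ld) + p_out * unif_dens;
      if (dens <= 0.0) return R_NegInf;
      ll += std::log(dens);
    } else {
      if (ld == R_NegInf) return R_NegInf;
      ll += ld;
    }
    double pe = feedback[i] - q[chosen[i]];
    double rate = pe > 0.0 ? eta_pos : (pe < 0.0 ? eta_neg : 0.0);
    q[chosen[i]] += rate * pe;
  }
  return ll;
}

// Q-value trajectory for one subject (used by predict/diagnostic code):
// returns the trial drift rate before each update.
// [[Rcpp::export(name = ".trial_drifts_cpp")]]
NumericVector trial_drifts_cpp(IntegerVector chosen, IntegerVector better,
                               IntegerVector worse, NumericVector feedback,
                               int n_symbols,
                               double eta_pos, double eta_neg,
                               double v_scaling) {
  R_xlen_t n = chosen.size();
  std::vector<double> q(n_symbols, 0.5);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = (q[better[i]] - q[worse[i]]) * v_scaling;
    double pe = feedback[i] - q[chosen[i]];
    double rate = pe > 0.0 ? eta_pos : (pe < 0.0 ? eta_neg : 0.0);
    q[chosen[i]] += rate * pe;
  }
  return out;
}
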