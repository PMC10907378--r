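#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Forward AR(2) synthesis: c_t = s_t + g1*c_{t-1} + g2*c_{t-2}, zero history.
// Columns of the implied matrix K are shifted copies of the AR(2) impulse
// response, so c = K s.
static void ar2_apply(const std::vector<double>& s, double g1, double g2,
                      std::vector<double>& c) {
  const int T = (int)s.size();
  c.assign(T, 0.0);
  for (int t = 0; t < T; ++t) {
    double v = s[t];
    if (t >= 1) v += g1 * c[t - 1];
    if (t >= 2) v += g2 * c[t - 2];
    c[t] = v;
  }
}

// Adjoint: w = K' r runs the same recursion backwards in time.
static void ar2_adjoint(const std::vector<double>& r, double g1, double g2,
                        std::vector<double>& w) {
  const int T = (int)r.size();
  w.assign(T, 0.0);
  for (int t = T - 1; t >= 0; --t) {
    double v = r[t];
    if (t + 1 < T) v += g1 * w[t + 1];
    if (t + 2 < T) v += g2 * w[t + 2];
    w[t] = v;
  }
}

// [[Rcpp::export]]
NumericVector ar2_filter_cpp(NumericVector s, double g1, double g2) {
  std::vector<double> sv(s.begin(), s.end()), c;
  ar2_apply(sv, g1, g2, c);
  return wrap(c);
}

static double lipschitz_ar2(double g1, double g2, int T) {
  // power iteration on K'K
  std::vector<double> x(T), kx, ktkx;
  for (int t = 0; t < T; ++t) x[t] = 1.0 / std::sqrt((double)T);
  double lam = 1.0;
  for (int it = 0; it < 30; ++it) {
    ar2_apply(x, g1, g2, kx);
    ar2_adjoint(kx, g1, g2, ktkx);
    double nrm = 0.0;
    for (int t = 0; t < T; ++t) nrm += ktkx[t] * ktkx[t];
    nrm = std::sqrt(nrm);
    if (nrm == 0.0) return 1.0;
    lam = nrm;
    for (int t = 0; t < T; ++t) x[t] = ktkx[t] / nrm;
  }
  return lam;
}

// Projected FISTA (with restart) for the non-negative sparse deconvolution
//   minimize 0.5*||K s + b - y||^2 + lambda * sum(s)   s.t.  s >= 0,
// optionally over the constant baseline b as well (fit_baseline; b is the
// exact minimiser mean(y - K s) given s, updated every iteration, keeping
// the problem jointly convex). Warm start via s0. Returns spikes s, fit
// c = K s + b, baseline, objective and iterations.
// [[Rcpp::export]]
List fista_deconv_cpp(NumericVector y, double g1, double g2, double lambda,
                      NumericVector s0, int max_iter = 5000,
                      double tol = 1e-10, bool fit_baseline = false) {
  const int T = y.size();
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> s(s0.begin(), s0.end());
  if ((int)s.size() != T) s.assign(T, 0.0);
  for (int t = 0; t < T; ++t) if (s[t] < 0) s[t] = 0;

  const double L = lipschitz_ar2(g1, g2, T) * 1.01;
  std::vector<double> z = s, s_prev = s, c, r, g;
  double tk = 1.0;
  double b = 0.0;

  auto baseline_for = [&](const std::vector<double>& cv) {
    if (!fit_baseline) return 0.0;
    double m = 0.0;
    for (int t = 0; t < T; ++t) m += yv[t] - cv[t];
    return m / T;
  };

  auto objective = [&](const std::vector<double>& sv) {
    ar2_apply(sv, g1, g2, c);
    double bb = baseline_for(c);
    double obj = 0.0;
    for (int t = 0; t < T; ++t) {
      double d = c[t] + bb - yv[t];
      obj += 0.5 * d * d + lambda * sv[t];
    }
    return obj;
  };

  double obj_prev = objective(s);
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    ar2_apply(z, g1, g2, c);
    b = baseline_for(c);
    r.resize(T);
    for (int t = 0; t < T; ++t) r[t] = c[t] + b - yv[t];
    ar2_adjoint(r, g1, g2, g);
    s_prev = s;
    for (int t = 0; t < T; ++t) {
      double v = z[t] - (g[t] + lambda) / L;
      s[t] = v > 0.0 ? v : 0.0;
    }
    double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    double mom = (tk - 1.0) / tk1;
    // restart if the objective went up (monotone safeguard every 10 iters)
    if (it % 10 == 9) {
      double obj = objective(s);
      if (obj > obj_prev) { tk1 = 1.0; mom = 0.0; z = s; }
      else {
        double rel = std::abs(obj_prev - obj) /
                     (std::abs(obj_prev) + 1e-300);
        if (rel < tol) { obj_prev = obj; ++it; break; }
      }
      obj_prev = obj;
    }
    for (int t = 0; t < T; ++t) z[t] = s[t] + mom * (s[t] - s_prev[t]);
    tk = tk1;
  }

  double obj = objective(s);  // refreshes c = K s and the baseline
  b = baseline_for(c);
  double rss = 0.0;
  for (int t = 0; t < T; ++t) {
    double d = c[t] + b - yv[t];
    rss += d * d;
  }
  for (int t = 0; t < T; ++t) c[t] += b;
  return List::create(_["spikes"] = wrap(s), _["fit"] = wrap(c),
                      _["baseline"] = b, _["objective"] = obj,
                      _["rss"] = rss, _["iterations"] = it);
}
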