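#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-dimensional Gaussian mixture EM on (log10-transformed) data.
//
// E- and M-steps are fused: component densities are evaluated directly
// (with a log-sum-exp fallback for events where every density underflows)
// and the weighted sufficient statistics (nk, sum r*y, sum r*y^2) are
// accumulated in the same pass, so no responsibility matrix is stored.
//
// Convergence: relative log-likelihood change below tol_rel, or the
// Aitken-accelerated estimate of the asymptotic log-likelihood within
// tol_aitken of the current value, capped at maxit iterations.
//
// Returns parameters at convergence plus the per-iteration log-likelihood
// trace so callers can assert monotone ascent.
// [[Rcpp::export]]
List em_gauss_mix(NumericVector y, NumericVector mu0, NumericVector sigma0,
                  NumericVector w0, double tol_rel, double tol_aitken,
                  int maxit, double sigma_floor) {
  const int n = y.size();
  const int k = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sigma(sigma0.begin(), sigma0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> amp(k), inv2v(k), lamp(k);
  std::vector<double> nk(k), s1(k), s2(k), e(k);
  std::vector<double> ll_trace;
  ll_trace.reserve(64);
  const double inv_sqrt2pi = 1.0 / std::sqrt(2.0 * M_PI);
  double ll_prev = R_NegInf, ll_prev2 = R_NegInf, ll_last = R_NegInf;

  for (int iter = 0; iter < maxit; ++iter) {
    for (int j = 0; j < k; ++j) {
      amp[j] = std::max(w[j], 1e-300) * inv_sqrt2pi / sigma[j];
      lamp[j] = std::log(amp[j]);
      inv2v[j] = 0.5 / (sigma[j] * sigma[j]);
      nk[j] = s1[j] = s2[j] = 0.0;
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double yi = y[i], yi2 = yi * yi;
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        double d = yi - mu[j];
        double ej = amp[j] * std::exp(-d * d * inv2v[j]);
        e[j] = ej;
        s += ej;
      }
      if (s > 0.0 && std::isfinite(s)) {
        ll += std::log(s);
      } else {
        // every density underflowed: recompute with a max shift
        double m = R_NegInf;
        for (int j = 0; j < k; ++j) {
          double d = yi - mu[j];
          double lp = lamp[j] - d * d * inv2v[j];
          e[j] = lp;
          if (lp > m) m = lp;
        }
        s = 0.0;
        for (int j = 0; j < k; ++j) {
          e[j] = std::exp(e[j] - m);
          s += e[j];
        }
        ll += m + std::log(s);
      }
      const double inv_s = 1.0 / s;
      for (int j = 0; j < k; ++j) {
        double r = e[j] * inv_s;
        nk[j] += r;
        s1[j] += r * yi;
        s2[j] += r * yi2;
      }
    }
    ll_trace.push_back(ll);
    ll_last = ll;

    if (iter >= 1) {
      double denom = std::fabs(ll_prev) > 1.0 ? std::fabs(ll_prev) : 1.0;
      if (std::fabs(ll - ll_prev) / denom < tol_rel) break;
      if (iter >= 2) {
        double d1 = ll_prev - ll_prev2, d2 = ll - ll_prev;
        if (d1 > 0.0 && d2 > 0.0 && d2 < d1) {
          double a = d2 / d1;
          double ll_inf = ll_prev + d2 / (1.0 - a);
          if (std::fabs(ll_inf - ll) < tol_aitken) break;
        }
      }
    }
    ll_prev2 = ll_prev;
    ll_prev = ll;

    // M-step from the accumulated sufficient statistics
    for (int j = 0; j < k; ++j) {
      double nkj = nk[j] < 1e-10 ? 1e-10 : nk[j];
      double m_new = s1[j] / nkj;
      double var = s2[j] / nkj - m_new * m_new;
      if (var < 0.0) var = 0.0;
      mu[j] = m_new;
      sigma[j] = std::sqrt(var);
      if (sigma[j] < sigma_floor) sigma[j] = sigma_floor;
      w[j] = nkj / n;
    }
    double wsum = 0.0;
    for (int j = 0; j < k; ++j) wsum += w[j];
    for (int j = 0; j < k; ++j) w[j] /= wsum;
  }

  return List::create(
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["sigma"] = NumericVector(sigma.begin(), sigma.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["loglik"] = ll_last,
    _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["iterations"] = static_cast<int>(ll_trace.size()));
}
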