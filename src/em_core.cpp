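#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// EM for a K-component normal mixture on log-transformed data.
//
// One call runs a single EM trajectory from the supplied starting values.
// The E-step computes responsibilities with the log-sum-exp trick; the
// M-step updates (pi, mu, sigma) with the usual weighted moments, flooring
// sigma at sigma_floor. Terminates when the relative log-likelihood
// improvement drops below tol or after max_iter iterations.
//
// Returns the parameter estimates, the per-iteration log-likelihood trace,
// and flags recording whether any component sits at the sigma floor or
// below the weight floor at termination (degenerate solutions are reported,
// not silently accepted).
// [[Rcpp::export(name = ".em_run_cpp")]]
List em_run_cpp(NumericVector x, NumericVector mu0, NumericVector sigma0,
                NumericVector pi0, double tol, int max_iter,
                double sigma_floor, double weight_floor) {
  const int n = x.size();
  const int K = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sigma(sigma0.begin(), sigma0.end());
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> resp(static_cast<size_t>(n) * K);
  std::vector<double> lp(K);
  std::vector<double> trace;
  trace.reserve(64);

  const double LOG_2PI = 1.8378770664093454836;
  double loglik = R_NegInf;
  bool tol_met = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // E-step + observed-data log-likelihood
    double ll = 0.0;
    std::vector<double> logpi(K), logsig(K), inv2s2(K);
    for (int k = 0; k < K; ++k) {
      logpi[k] = std::log(pi[k]);
      logsig[k] = std::log(sigma[k]);
      inv2s2[k] = 0.5 / (sigma[k] * sigma[k]);
    }
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double d = x[i] - mu[k];
        lp[k] = logpi[k] - logsig[k] - 0.5 * LOG_2PI - d * d * inv2s2[k];
        if (lp[k] > m) m = lp[k];
      }
      if (!std::isfinite(m)) {
        // all-zero row: numerically impossible density
        return List::create(_["status"] = "degenerate",
                            _["iter"] = iter);
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(lp[k] - m);
      double lse = m + std::log(s);
      ll += lse;
      for (int k = 0; k < K; ++k)
        resp[static_cast<size_t>(i) * K + k] = std::exp(lp[k] - lse);
    }
    trace.push_back(ll);

    // convergence on relative improvement
    if (iter > 0) {
      double rel = std::fabs(ll - loglik) /
                   (std::fabs(loglik) > 1.0 ? std::fabs(loglik) : 1.0);
      if (rel < tol) { loglik = ll; tol_met = true; break; }
    }
    loglik = ll;

    // M-step
    for (int k = 0; k < K; ++k) {
      double w = 0.0, wx = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = resp[static_cast<size_t>(i) * K + k];
        w += r;
        wx += r * x[i];
      }
      double nk = w;
      double mk = (nk > 0.0) ? wx / nk : mu[k];
      double wv = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = resp[static_cast<size_t>(i) * K + k];
        double d = x[i] - mk;
        wv += r * d * d;
      }
      double sk = (nk > 0.0) ? std::sqrt(wv / nk) : sigma_floor;
      pi[k] = nk / n;
      mu[k] = mk;
      sigma[k] = (sk < sigma_floor) ? sigma_floor : sk;
    }
  }

  bool at_sigma_floor = false, at_weight_floor = false;
  for (int k = 0; k < K; ++k) {
    if (sigma[k] <= sigma_floor) at_sigma_floor = true;
    if (pi[k] < weight_floor) at_weight_floor = true;
  }

  return List::create(
      _["status"] = "ok",
      _["mu"] = NumericVector(mu.begin(), mu.end()),
      _["sigma"] = NumericVector(sigma.begin(), sigma.end()),
      _["pi"] = NumericVector(pi.begin(), pi.end()),
      _["loglik"] = loglik,
      _["trace"] = NumericVector(trace.begin(), trace.end()),
      _["n_iter"] = static_cast<int>(trace.size()),
      _["tol_met"] = tol_met,
      _["at_sigma_floor"] = at_sigma_floor,
      _["at_weight_floor"] = at_weight_floor);
}
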