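// Metropolis-within-Gibbs sampler for the Bayesian Cox model with a
// gamma-process baseline, in the counting-process (piecewise-exponential)
// representation. Event times are grouped on the grid of unique event times
// (Breslow-style); the baseline hazard increment of interval k has an
// independent Gamma(c * lambda_star * dt_k, c) prior and a conjugate Gibbs
// update Gamma(c * lambda_star * dt_k + d_k, c + R_k(beta)), where R_k is
// the at-risk sum of exp(linear predictor). Regression coefficients get
// Normal(0, prior_sd^2) priors and adaptive random-walk Metropolis updates.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
List cox_mcmc_cpp(NumericVector time, IntegerVector event, NumericMatrix X,
                  NumericVector grid, IntegerVector d_events,
                  NumericVector dt, double c_conf, double lambda_star,
                  int n_iter, int n_burn, int thin, double prior_sd_beta) {
  const int n = time.size();
  const int p = X.ncol();
  const int K = grid.size();

  // subjects ordered by time descending, for O(n + K) at-risk sums
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return time[a] > time[b]; });

  std::vector<double> beta(p, 0.0), lp(n, 0.0), elp(n, 1.0);
  std::vector<double> h(K), R(K, 0.0);
  for (int k = 0; k < K; ++k) h[k] = lambda_star * dt[k];

  auto risk_sums = [&](const std::vector<double>& e, std::vector<double>& out) {
    double acc = 0;
    int ptr = 0;
    for (int k = K - 1; k >= 0; --k) {
      while (ptr < n && time[idx[ptr]] >= grid[k]) {
        acc += e[idx[ptr]];
        ptr++;
      }
      out[k] = acc;
    }
  };
  risk_sums(elp, R);

  // sum of X over events, for fast Metropolis increments
  std::vector<double> xev(p, 0.0);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      if (event[i]) xev[j] += X(i, j);

  std::vector<double> psd(p, 0.2);
  std::vector<int> acc_b(p, 0), att_b(p, 0);

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix bdraws(n_keep, p), hdraws(n_keep, K);
  NumericVector dev(n_keep);
  int keep = 0;

  std::vector<double> elp_new(n), R_new(K);

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < p; ++j) {
      att_b[j]++;
      double prop = beta[j] + R::rnorm(0.0, psd[j]);
      double delta = prop - beta[j];
      for (int i = 0; i < n; ++i)
        elp_new[i] = elp[i] * std::exp(delta * X(i, j));
      risk_sums(elp_new, R_new);
      double dll = delta * xev[j];
      for (int k = 0; k < K; ++k) dll -= h[k] * (R_new[k] - R[k]);
      dll += R::dnorm(prop, 0.0, prior_sd_beta, 1) -
             R::dnorm(beta[j], 0.0, prior_sd_beta, 1);
      if (std::log(R::runif(0, 1)) < dll) {
        beta[j] = prop;
        for (int i = 0; i < n; ++i) {
          lp[i] += delta * X(i, j);
          elp[i] = elp_new[i];
        }
        std::swap(R, R_new);
        acc_b[j]++;
      }
    }
    // conjugate update of the baseline increments
    for (int k = 0; k < K; ++k) {
      double shape = c_conf * lambda_star * dt[k] + d_events[k];
      double rate = c_conf + R[k];
      h[k] = R::rgamma(shape, 1.0 / rate);
    }

    if (it < n_burn && (it + 1) % 50 == 0) {
      for (int j = 0; j < p; ++j) {
        if (att_b[j] > 0) {
          double rate = double(acc_b[j]) / att_b[j];
          psd[j] *= std::exp(0.5 * (rate - 0.3));
          psd[j] = std::min(std::max(psd[j], 1e-4), 10.0);
          acc_b[j] = att_b[j] = 0;
        }
      }
    }

    if (it >= n_burn && (it - n_burn) % thin == 0 && keep < n_keep) {
      for (int j = 0; j < p; ++j) bdraws(keep, j) = beta[j];
      double ll = 0;
      for (int k = 0; k < K; ++k) {
        hdraws(keep, k) = h[k];
        ll += d_events[k] * std::log(h[k]) - h[k] * R[k];
      }
      for (int i = 0; i < n; ++i)
        if (event[i]) ll += lp[i];
      dev[keep] = -2.0 * ll;
      keep++;
    }
  }

  return List::create(_["beta"] = bdraws, _["h"] = hdraws,
                      _["deviance"] = dev);
}

// [[Rcpp::export]]
double cox_loglik_cpp(NumericVector time, IntegerVector event,
                      NumericVector lp, NumericVector grid,
                      IntegerVector d_events, NumericVector h) {
  const int n = time.size();
  const int K = grid.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return time[a] > time[b]; });
  double acc = 0, ll = 0;
  int ptr = 0;
  for (int k = K - 1; k >= 0; --k) {
    while (ptr < n && time[idx[ptr]] >= grid[k]) {
      acc += std::exp(lp[idx[ptr]]);
      ptr++;
    }
    ll += d_events[k] * std::log(h[k]) - h[k] * acc;
  }
  for (int i = 0; i < n; ++i)
    if (event[i]) ll += lp[i];
  return ll;
}
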