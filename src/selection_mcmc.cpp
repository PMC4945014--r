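// Metropolis-within-Gibbs sampler for the three-state tree-use model.
//
// The categorical likelihood over states {U, F, O} factorizes: given
// availability a=1 and no previous-period use (f=0), the W-part is a
// Bernoulli likelihood of "used" with P = plogis(lp), and the foraging-mode
// part contributes v for F trees and (1-v) for O trees. v is conjugate
// (Beta) and independent of the regression block, so it is Gibbs-updated.
// Fixed effects carry optional Kuo-Mallick inclusion indicators with
// Bernoulli(0.5) priors; the woodpecker random intercepts are Gaussian with
// a half-Normal hyperprior on their SD.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double ll_bern(double lp, int used) {
  return used ? -log1p(std::exp(-lp)) : -log1p(std::exp(lp));
}

// [[Rcpp::export]]
List selection_mcmc_cpp(IntegerVector used, NumericMatrix X,
                        LogicalVector indicator, IntegerVector group,
                        int n_groups, int nF, int nO,
                        int n_iter, int n_burn, int thin,
                        double prior_sd_beta, double prior_scale_sdg) {
  const int n = used.size();
  const int p = X.ncol();
  const bool has_groups = n_groups > 0;

  std::vector< std::vector<int> > grows(n_groups);
  if (has_groups)
    for (int i = 0; i < n; ++i) grows[group[i]].push_back(i);

  std::vector<double> beta(p, 0.0), gamma(n_groups, 0.0);
  std::vector<int> g(p, 1);
  double sdg = 1.0, v = 0.5;
  std::vector<double> lp(n, 0.0);

  std::vector<double> psd_beta(p, 0.2), psd_gamma(n_groups, 0.3);
  double psd_sdg = 0.3;
  std::vector<int> acc_b(p, 0), att_b(p, 0), acc_g(n_groups, 0),
      att_g(n_groups, 0);
  int acc_s = 0, att_s = 0;

  auto ll_total = [&]() {
    double s = 0;
    for (int i = 0; i < n; ++i) s += ll_bern(lp[i], used[i]);
    return s;
  };
  double ll_cur = ll_total();

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix draws(n_keep, p + n_groups + 2);
  IntegerMatrix ind_draws(n_keep, p);
  NumericVector dev(n_keep);
  int keep = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // fixed effects
    for (int j = 0; j < p; ++j) {
      if (indicator[j] && g[j] == 0) {
        // likelihood flat in beta_j: conditional = prior
        beta[j] = R::rnorm(0.0, prior_sd_beta);
      } else {
        att_b[j]++;
        double prop = beta[j] + R::rnorm(0.0, psd_beta[j]);
        double delta = prop - beta[j];
        double ll_new = 0;
        for (int i = 0; i < n; ++i)
          ll_new += ll_bern(lp[i] + delta * X(i, j), used[i]);
        double lpr = R::dnorm(prop, 0.0, prior_sd_beta, 1) -
                     R::dnorm(beta[j], 0.0, prior_sd_beta, 1);
        if (std::log(R::runif(0, 1)) < ll_new - ll_cur + lpr) {
          for (int i = 0; i < n; ++i) lp[i] += delta * X(i, j);
          beta[j] = prop;
          ll_cur = ll_new;
          acc_b[j]++;
        }
      }
      if (indicator[j]) {
        // Gibbs flip of the inclusion indicator (prior Bernoulli(0.5))
        double sgn = g[j] == 1 ? -1.0 : 1.0;  // toggle direction
        double ll_other = 0;
        for (int i = 0; i < n; ++i)
          ll_other += ll_bern(lp[i] + sgn * beta[j] * X(i, j), used[i]);
        double ll_in = g[j] == 1 ? ll_cur : ll_other;
        double ll_out = g[j] == 1 ? ll_other : ll_cur;
        double m = std::max(ll_in, ll_out);
        double p1 = std::exp(ll_in - m) /
                    (std::exp(ll_in - m) + std::exp(ll_out - m));
        int gnew = R::runif(0, 1) < p1 ? 1 : 0;
        if (gnew != g[j]) {
          for (int i = 0; i < n; ++i) lp[i] += sgn * beta[j] * X(i, j);
          ll_cur = ll_other;
          g[j] = gnew;
        }
      }
    }
    // random intercepts per woodpecker
    if (has_groups) {
      for (int k = 0; k < n_groups; ++k) {
        att_g[k]++;
        double prop = gamma[k] + R::rnorm(0.0, psd_gamma[k]);
        double delta = prop - gamma[k];
        double dll = 0;
        for (int i : grows[k])
          dll += ll_bern(lp[i] + delta, used[i]) - ll_bern(lp[i], used[i]);
        dll += R::dnorm(prop, 0.0, sdg, 1) - R::dnorm(gamma[k], 0.0, sdg, 1);
        if (std::log(R::runif(0, 1)) < dll) {
          for (int i : grows[k]) lp[i] += delta;
          gamma[k] = prop;
          acc_g[k]++;
        }
      }
      ll_cur = ll_total();  // refresh the cached data likelihood
      // half-Normal(0, prior_scale_sdg) hyperprior, log-scale random walk
      att_s++;
      double lprop = std::log(sdg) + R::rnorm(0.0, psd_sdg);
      double sprop = std::exp(lprop);
      double dpost = 0;
      for (int k = 0; k < n_groups; ++k)
        dpost += R::dnorm(gamma[k], 0.0, sprop, 1) -
                 R::dnorm(gamma[k], 0.0, sdg, 1);
      dpost += R::dnorm(sprop, 0.0, prior_scale_sdg, 1) -
               R::dnorm(sdg, 0.0, prior_scale_sdg, 1);
      dpost += lprop - std::log(sdg);  // Jacobian of the log transform
      if (std::log(R::runif(0, 1)) < dpost) { sdg = sprop; acc_s++; }
    }
    // foraging-mode probability: conjugate Beta update
    v = R::rbeta(1.0 + nF, 1.0 + nO);

    // proposal adaptation during burn-in (target ~30% acceptance)
    if (it < n_burn && (it + 1) % 50 == 0) {
      for (int j = 0; j < p; ++j) {
        if (att_b[j] > 0) {
          double rate = double(acc_b[j]) / att_b[j];
          psd_beta[j] *= std::exp(0.5 * (rate - 0.3));
          psd_beta[j] = std::min(std::max(psd_beta[j], 1e-4), 10.0);
          acc_b[j] = att_b[j] = 0;
        }
      }
      for (int k = 0; k < n_groups; ++k) {
        if (att_g[k] > 0) {
          double rate = double(acc_g[k]) / att_g[k];
          psd_gamma[k] *= std::exp(0.5 * (rate - 0.3));
          psd_gamma[k] = std::min(std::max(psd_gamma[k], 1e-4), 10.0);
          acc_g[k] = att_g[k] = 0;
        }
      }
      if (att_s > 0) {
        psd_sdg *= std::exp(0.5 * (double(acc_s) / att_s - 0.3));
        psd_sdg = std::min(std::max(psd_sdg, 1e-4), 5.0);
        acc_s = att_s = 0;
      }
    }

    if (it >= n_burn && (it - n_burn) % thin == 0 && keep < n_keep) {
      for (int j = 0; j < p; ++j) {
        draws(keep, j) = beta[j];
        ind_draws(keep, j) = indicator[j] ? g[j] : 1;
      }
      for (int k = 0; k < n_groups; ++k) draws(keep, p + k) = gamma[k];
      draws(keep, p + n_groups) = sdg;
      draws(keep, p + n_groups + 1) = v;
      double d = -2.0 * (ll_cur + nF * std::log(v) + nO * std::log1p(-v));
      dev[keep] = d;
      keep++;
    }
  }

  return List::create(_["draws"] = draws, _["indicators"] = ind_draws,
                      _["deviance"] = dev);
}

// [[Rcpp::export]]
double selection_loglik_cpp(NumericVector lp, IntegerVector used) {
  double s = 0;
  for (int i = 0; i < lp.size(); ++i) s += ll_bern(lp[i], used[i]);
  return s;
}
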