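// Adaptive Metropolis-within-Gibbs sampler for the hierarchical Gaussian
// fitness-curve model:
//
//   Z_i = A * exp(-((x_i - lambda_{j(i)}) / sigma)^2)
//   lambda_j = mu + B * theta_j + u_j,  u_j ~ N_[-2,2](0, sigma2U)
//   Y_i ~ Poisson(Z_i)  or  Y_i ~ Binomial(n_i, Z_i)
//
// Priors: mu ~ U(-2,2), sigma ~ U(0,100), A ~ U(0,Amax),
// 1/sigma2U ~ Gamma(0.001, 0.001), B ~ N(0, 1e6).
//
// Bounded parameters use random-walk proposals with reflection at the prior
// bounds; proposal scales are adapted during burn-in only (target acceptance
// ~0.44). RNG is R's own stream, so reproducibility is governed by set.seed()
// on the R side.

#include <Rcpp.h>
using namespace Rcpp;

static inline double reflect(double x, double lo, double hi) {
  double range = hi - lo;
  if (range <= 0) return lo;
  // fold into [lo, lo + 2*range) then reflect the upper half
  double period = 2.0 * range;
  double t = (x - lo) - period * std::floor((x - lo) / period);
  return (t < range) ? lo + t : hi - (t - range);
}

struct OptimumData {
  NumericVector x;      // standardized lay date
  IntegerVector year;   // 0-based year index
  NumericVector y;      // response
  NumericVector trials; // binomial trials (ignored for poisson)
  int family;           // 0 = poisson, 1 = binomial
  int J;
  std::vector<std::vector<int>> by_year;
};

// log-likelihood over a subset of observations (all if idx == nullptr)
static double loglik_subset(const OptimumData& d,
                            const std::vector<double>& lambda,
                            double A, double sigma,
                            const std::vector<int>* idx) {
  double ll = 0.0;
  size_t n = idx ? idx->size() : (size_t)d.x.size();
  for (size_t k = 0; k < n; ++k) {
    int i = idx ? (*idx)[k] : (int)k;
    double dev = (d.x[i] - lambda[d.year[i]]) / sigma;
    double z = A * std::exp(-dev * dev);
    if (d.family == 0) {
      ll += d.y[i] * std::log(z) - z;
    } else {
      if (z >= 1.0) z = 1.0 - 1e-12;
      ll += d.y[i] * std::log(z) + (d.trials[i] - d.y[i]) * std::log1p(-z);
    }
  }
  return ll;
}

// log prior density of sigma2U under 1/sigma2U ~ Gamma(shape, rate),
// plus the truncated-normal normalisation for the J year effects
static double log_sigma2U_terms(double s2, const std::vector<double>& u,
                                double shape, double rate) {
  double lp = (-shape - 1.0) * std::log(s2) - rate / s2;
  double s = std::sqrt(s2);
  double lnorm = std::log(R::pnorm(2.0, 0.0, s, 1, 0) -
                          R::pnorm(-2.0, 0.0, s, 1, 0));
  for (size_t j = 0; j < u.size(); ++j) {
    lp += R::dnorm(u[j], 0.0, s, 1) - lnorm;
  }
  return lp;
}

// [[Rcpp::export]]
List optimum_mcmc_cpp(NumericVector x, IntegerVector year, NumericVector y,
                      NumericVector trials, int family, int J, double Amax,
                      NumericVector theta, bool use_cue, bool sample_u,
                      double fix_A, double fix_sigma,
                      int n_iter, int burnin, int thin) {
  OptimumData d;
  d.x = x; d.year = year; d.y = y; d.trials = trials;
  d.family = family; d.J = J;
  d.by_year.assign(J, std::vector<int>());
  for (int i = 0; i < x.size(); ++i) d.by_year[year[i]].push_back(i);

  const double prior_shape = 0.001, prior_rate = 0.001;
  bool A_fixed = R_finite(fix_A);
  bool sigma_fixed = R_finite(fix_sigma);

  // initial values (dispersed around the prior middle)
  double mu = R::runif(-1.0, 1.0);
  double sigma = sigma_fixed ? fix_sigma : R::runif(0.5, 2.0);
  double A = A_fixed ? fix_A : R::runif(0.2 * Amax, 0.8 * Amax);
  double s2U = 0.1;
  double B = 0.0;
  std::vector<double> u(J, 0.0);
  if (sample_u) for (int j = 0; j < J; ++j) u[j] = R::runif(-0.2, 0.2);

  std::vector<double> lambda(J);
  auto update_lambda = [&]() {
    for (int j = 0; j < J; ++j)
      lambda[j] = mu + (use_cue ? B * theta[j] : 0.0) + u[j];
  };
  update_lambda();
  double ll = loglik_subset(d, lambda, A, sigma, nullptr);

  // adaptive proposal scales
  double sd_mu = 0.1, sd_sigma = 0.1, sd_A = 0.1 * Amax, sd_B = 0.1,
         sd_ls2U = 0.5;
  std::vector<double> sd_u(J, 0.2);
  int acc_mu = 0, acc_sigma = 0, acc_A = 0, acc_B = 0, acc_ls2U = 0;
  std::vector<int> acc_u(J, 0);
  const int adapt_every = 50;
  auto adapt = [](double& sd, int& acc, double sd_max) {
    double rate = acc / (double)50;
    sd *= std::exp(0.5 * (rate - 0.44));
    if (sd < 1e-6) sd = 1e-6;
    if (sd > sd_max) sd = sd_max;
    acc = 0;
  };

  int n_keep = (n_iter - burnin + thin - 1) / thin;
  if (n_keep < 0) n_keep = 0;
  int n_par = 5 + (use_cue ? 1 : 0) + J;  // mu, sigma, A, s2U, ll, (B), u_j
  NumericMatrix draws(n_keep, n_par);
  int row = 0;

  for (int it = 0; it < n_iter; ++it) {
    // -- mu --
    {
      double prop = reflect(mu + R::norm_rand() * sd_mu, -2.0, 2.0);
      double mu_old = mu;
      mu = prop; update_lambda();
      double ll_new = loglik_subset(d, lambda, A, sigma, nullptr);
      if (std::log(R::unif_rand()) < ll_new - ll) { ll = ll_new; ++acc_mu; }
      else { mu = mu_old; update_lambda(); }
    }
    // -- sigma --
    if (!sigma_fixed) {
      double prop = reflect(sigma + R::norm_rand() * sd_sigma, 0.0, 100.0);
      double ll_new = loglik_subset(d, lambda, A, prop, nullptr);
      if (std::log(R::unif_rand()) < ll_new - ll) {
        sigma = prop; ll = ll_new; ++acc_sigma;
      }
    }
    // -- A --
    if (!A_fixed) {
      double prop = reflect(A + R::norm_rand() * sd_A, 0.0, Amax);
      double ll_new = loglik_subset(d, lambda, prop, sigma, nullptr);
      if (std::log(R::unif_rand()) < ll_new - ll) {
        A = prop; ll = ll_new; ++acc_A;
      }
    }
    // -- B (cue slope) --
    if (use_cue) {
      double prop = B + R::norm_rand() * sd_B;
      double B_old = B;
      double lp_old = R::dnorm(B, 0.0, 1000.0, 1);
      B = prop; update_lambda();
      double ll_new = loglik_subset(d, lambda, A, sigma, nullptr);
      double lp_new = R::dnorm(B, 0.0, 1000.0, 1);
      if (std::log(R::unif_rand()) < (ll_new + lp_new) - (ll + lp_old)) {
        ll = ll_new; ++acc_B;
      } else { B = B_old; update_lambda(); }
    }
    // -- u_j (per-year optimum deviations) --
    if (sample_u) {
      double sU = std::sqrt(s2U);
      for (int j = 0; j < J; ++j) {
        double prop = reflect(u[j] + R::norm_rand() * sd_u[j], -2.0, 2.0);
        double lam_old = lambda[j], u_old = u[j];
        double ll_old_j = loglik_subset(d, lambda, A, sigma, &d.by_year[j]);
        u[j] = prop;
        lambda[j] = mu + (use_cue ? B * theta[j] : 0.0) + u[j];
        double ll_new_j = loglik_subset(d, lambda, A, sigma, &d.by_year[j]);
        double lp = R::dnorm(prop, 0.0, sU, 1) - R::dnorm(u_old, 0.0, sU, 1);
        if (std::log(R::unif_rand()) < ll_new_j - ll_old_j + lp) {
          ll += ll_new_j - ll_old_j; ++acc_u[j];
        } else { u[j] = u_old; lambda[j] = lam_old; }
      }
      // -- sigma2U (log-scale random walk) --
      // The Gamma(0.001, 0.001) precision prior is nearly log-flat over an
      // enormous range while the truncated-normal likelihood saturates for
      // large sigma2U; reflect the log variance inside generous numerical
      // bounds (u_j lives on [-2,2], so sigma2U beyond 1e6 is meaningless)
      // to keep the walk from stranding on the flat plateau.
      {
        double ls = std::log(s2U);
        double prop = reflect(ls + R::norm_rand() * sd_ls2U,
                              std::log(1e-8), std::log(1e6));
        double lp_old = log_sigma2U_terms(s2U, u, prior_shape, prior_rate) + ls;
        double lp_new = log_sigma2U_terms(std::exp(prop), u, prior_shape,
                                          prior_rate) + prop;
        if (std::log(R::unif_rand()) < lp_new - lp_old) {
          s2U = std::exp(prop); ++acc_ls2U;
        }
      }
    }

    if (it < burnin && (it + 1) % adapt_every == 0) {
      adapt(sd_mu, acc_mu, 4.0);
      if (!sigma_fixed) adapt(sd_sigma, acc_sigma, 50.0);
      if (!A_fixed) adapt(sd_A, acc_A, Amax);
      if (use_cue) adapt(sd_B, acc_B, 10.0);
      if (sample_u) {
        for (int j = 0; j < J; ++j) adapt(sd_u[j], acc_u[j], 4.0);
        adapt(sd_ls2U, acc_ls2U, 2.0);
      }
    }

    if (it >= burnin && (it - burnin) % thin == 0 && row < n_keep) {
      int c = 0;
      draws(row, c++) = mu;
      draws(row, c++) = sigma;
      draws(row, c++) = A;
      draws(row, c++) = s2U;
      draws(row, c++) = ll;
      if (use_cue) draws(row, c++) = B;
      for (int j = 0; j < J; ++j) draws(row, c++) = u[j];
      ++row;
    }
  }

  CharacterVector nm(n_par);
  int c = 0;
  nm[c++] = "mu"; nm[c++] = "sigma"; nm[c++] = "A"; nm[c++] = "sigma2_U";
  nm[c++] = "loglik";
  if (use_cue) nm[c++] = "B";
  for (int j = 0; j < J; ++j) nm[c++] = "u_" + std::to_string(j + 1);
  colnames(draws) = nm;

  return List::create(_["draws"] = draws);
}
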