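#include <Rcpp.h>
using namespace Rcpp;

// Truncated-normal draw by CDF inversion, clamped away from degenerate tails.
static double rtnorm1(double mean, double sd, double lo, double hi) {
  double plo = (lo == R_NegInf) ? 0.0 : R::pnorm((lo - mean) / sd, 0.0, 1.0, 1, 0);
  double phi = (hi == R_PosInf) ? 1.0 : R::pnorm((hi - mean) / sd, 0.0, 1.0, 1, 0);
  if (plo > 1.0 - 1e-14) plo = 1.0 - 1e-14;
  if (phi < plo + 1e-14) phi = plo + 1e-14;
  double u = R::runif(plo, phi);
  if (u <= 0.0) u = 1e-300;
  if (u >= 1.0) u = 1.0 - 1e-16;
  double x = mean + sd * R::qnorm(u, 0.0, 1.0, 1, 0);
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

// Gibbs sampler for a 3-component Gaussian mixture with the ordering
// constraint mu1 <= mu0 <= mu2 (component 0 = null/centre). Conjugate
// updates: Dirichlet on weights, truncated normal on means, inverse-gamma
// on variances. Uses R's RNG, so set.seed() on the R side fixes the chain.
// Returns the retained draws, one row per post-burn-in iteration, columns
// pi0 pi1 pi2 mu0 mu1 mu2 sigma0 sigma1 sigma2.
// [[Rcpp::export]]
NumericMatrix gibbs_mixture_chain(NumericVector z,
                                  int iterations,
                                  int burnin,
                                  NumericVector mu_prior_mean,
                                  NumericVector mu_prior_sd,
                                  double sigma_prior_shape,
                                  double sigma_prior_rate,
                                  NumericVector dirichlet_alpha) {
  const int m = z.size();

  // moment-based initial values
  double zm = 0.0, zs = 0.0;
  for (int i = 0; i < m; ++i) zm += z[i];
  zm /= m;
  for (int i = 0; i < m; ++i) zs += (z[i] - zm) * (z[i] - zm);
  zs = std::sqrt(zs / std::max(m - 1, 1));
  if (zs <= 0.0) zs = 1.0;

  double pi[3] = {0.90, 0.05, 0.05};
  double mu[3] = {zm, zm - 2.0 * zs, zm + 2.0 * zs};
  double sig[3] = {zs, zs, zs};

  NumericMatrix out(iterations - burnin, 9);

  for (int it = 0; it < iterations; ++it) {
    // component assignments and sufficient statistics
    double n[3] = {0, 0, 0}, S[3] = {0, 0, 0}, SS[3] = {0, 0, 0};
    double logw[3], inv2s2[3];
    for (int j = 0; j < 3; ++j) {
      logw[j] = std::log(pi[j]) - std::log(sig[j]);
      inv2s2[j] = 0.5 / (sig[j] * sig[j]);
    }
    for (int i = 0; i < m; ++i) {
      double w0 = std::exp(logw[0] - inv2s2[0] * (z[i] - mu[0]) * (z[i] - mu[0]));
      double w1 = std::exp(logw[1] - inv2s2[1] * (z[i] - mu[1]) * (z[i] - mu[1]));
      double w2 = std::exp(logw[2] - inv2s2[2] * (z[i] - mu[2]) * (z[i] - mu[2]));
      double tot = w0 + w1 + w2;
      int c;
      if (tot <= 0.0 || !R_FINITE(tot)) {
        c = 0; // numerically degenerate point: park in the null component
      } else {
        double u = R::runif(0.0, tot);
        c = (u < w0) ? 0 : ((u < w0 + w1) ? 1 : 2);
      }
      n[c] += 1.0;
      S[c] += z[i];
      SS[c] += z[i] * z[i];
    }

    // mixture proportions
    double g[3], gtot = 0.0;
    for (int j = 0; j < 3; ++j) {
      g[j] = R::rgamma(dirichlet_alpha[j] + n[j], 1.0);
      if (g[j] <= 0.0) g[j] = 1e-300;
      gtot += g[j];
    }
    for (int j = 0; j < 3; ++j) pi[j] = g[j] / gtot;

    // means under the ordering constraint (null drawn first, bounded by the
    // previous outer means; outer means then bounded by the new null mean)
    double post_mean[3], post_sd[3];
    for (int j = 0; j < 3; ++j) {
      double tau2 = mu_prior_sd[j] * mu_prior_sd[j];
      double prec = n[j] / (sig[j] * sig[j]) + 1.0 / tau2;
      post_mean[j] = (S[j] / (sig[j] * sig[j]) + mu_prior_mean[j] / tau2) / prec;
      post_sd[j] = std::sqrt(1.0 / prec);
    }
    mu[0] = rtnorm1(post_mean[0], post_sd[0], mu[1], mu[2]);
    mu[1] = rtnorm1(post_mean[1], post_sd[1], R_NegInf, mu[0]);
    mu[2] = rtnorm1(post_mean[2], post_sd[2], mu[0], R_PosInf);

    // variances
    for (int j = 0; j < 3; ++j) {
      double rss = SS[j] - 2.0 * mu[j] * S[j] + n[j] * mu[j] * mu[j];
      if (rss < 0.0) rss = 0.0;
      double a_post = sigma_prior_shape + 0.5 * n[j];
      double b_post = sigma_prior_rate + 0.5 * rss;
      double s2 = b_post / R::rgamma(a_post, 1.0);
      if (!R_FINITE(s2) || s2 <= 1e-12) s2 = 1e-12;
      sig[j] = std::sqrt(s2);
    }

    if (it >= burnin) {
      int r = it - burnin;
      out(r, 0) = pi[0]; out(r, 1) = pi[1]; out(r, 2) = pi[2];
      out(r, 3) = mu[0]; out(r, 4) = mu[1]; out(r, 5) = mu[2];
      out(r, 6) = sig[0]; out(r, 7) = sig[1]; out(r, 8) = sig[2];
    }
  }
  return out;
}
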