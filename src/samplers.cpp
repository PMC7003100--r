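// Gibbs samplers for spike-and-slab whole-genome regressions.
// Two variants share the marker-update kernel:
//  * BayesCpi: common slab variance, inclusion probability updated from a
//    Beta full conditional, slab scale recomputed each iteration from the
//    current exclusion probability (prior heritability 0.5).
//  * BayesB: fixed exclusion probability, per-marker slab variances.
// All draws go through R's RNG so set.seed() gives bit-reproducible runs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List wgr_gibbs(const arma::vec& y,
               const arma::mat& X,
               int iters,
               int burnin,
               double nu0,
               double pi_null,
               bool update_pi,
               bool per_marker_var,
               double msx,
               double fix_sigb = -1.0,
               double fix_sige = -1.0) {
  const int n = y.n_elem;
  const int m = X.n_cols;
  const double vy = arma::var(y);
  const double Se_prior = 0.5 * vy;

  arma::vec xx(m);
  for (int j = 0; j < m; ++j) xx(j) = arma::dot(X.col(j), X.col(j));

  arma::vec b(m, arma::fill::zeros);
  arma::ivec delta(m, arma::fill::zeros);
  double mu = arma::mean(y);
  arma::vec e = y - mu;
  double sige = (fix_sige > 0) ? fix_sige : vy * 0.5;
  double sigb_common = (fix_sigb > 0) ? fix_sigb
    : 0.5 * vy / (msx * std::max(1e-8, 1.0 - pi_null));
  arma::vec sigb(m);
  sigb.fill(sigb_common);
  double pin = pi_null;

  arma::vec freq(m, arma::fill::zeros);
  arma::vec bhat(m, arma::fill::zeros);
  double mu_hat = 0.0, pi_hat = 0.0, sigb_hat = 0.0, sige_hat = 0.0;
  int kept = 0;

  for (int it = 0; it < iters; ++it) {
    // slab scale from the current exclusion probability (prior h2 = 0.5)
    double Sb = per_marker_var
      ? 0.5 * vy / msx
      : 0.5 * vy / (msx * std::max(1e-8, 1.0 - pin));

    for (int j = 0; j < m; ++j) {
      if (xx(j) <= 0) { b(j) = 0; delta(j) = 0; continue; }
      double bj_old = b(j);
      double r = arma::dot(X.col(j), e) + xx(j) * bj_old;
      double vb = sigb(j);
      double c = xx(j) + sige / vb;
      // log Bayes factor for inclusion, slab effect integrated out
      double logbf = 0.5 * (std::log(sige / (vb * c)) + r * r / (sige * c));
      double logodds = std::log(std::max(1e-300, 1.0 - pin)) -
        std::log(std::max(1e-300, pin)) + logbf;
      double pincl = 1.0 / (1.0 + std::exp(-logodds));
      double bj_new = 0.0;
      int dj = (R::unif_rand() < pincl) ? 1 : 0;
      if (dj == 1) {
        bj_new = r / c + R::norm_rand() * std::sqrt(sige / c);
      }
      delta(j) = dj;
      if (bj_new != bj_old) {
        e += X.col(j) * (bj_old - bj_new);
        b(j) = bj_new;
      }
    }

    // intercept
    double mu_step = arma::mean(e) + R::norm_rand() * std::sqrt(sige / n);
    mu += mu_step;
    e -= mu_step;

    int q = arma::sum(delta);

    // slab variance(s)
    if (fix_sigb <= 0) {
      if (per_marker_var) {
        for (int j = 0; j < m; ++j) {
          double ss = nu0 * Sb + b(j) * b(j);
          sigb(j) = ss / R::rchisq(nu0 + (delta(j) ? 1.0 : 0.0));
        }
      } else {
        double ssb = 0.0;
        for (int j = 0; j < m; ++j) if (delta(j)) ssb += b(j) * b(j);
        sigb_common = (nu0 * Sb + ssb) / R::rchisq(nu0 + q);
        sigb.fill(sigb_common);
      }
    }

    // exclusion probability (BayesCpi only)
    if (update_pi) {
      pin = R::rbeta(m - q + 1.0, q + 1.0);
    }

    // residual variance
    if (fix_sige <= 0) {
      double sse = arma::dot(e, e);
      sige = (nu0 * Se_prior + sse) / R::rchisq(nu0 + n);
    }
    if (!std::isfinite(sige) || sige <= 0) {
      stop("divergent residual variance draw at iteration %d", it + 1);
    }

    if (it >= burnin) {
      ++kept;
      for (int j = 0; j < m; ++j) {
        if (delta(j)) freq(j) += 1.0;
        bhat(j) += b(j);
      }
      mu_hat += mu;
      pi_hat += pin;
      sigb_hat += (per_marker_var ? arma::mean(sigb) : sigb_common);
      sige_hat += sige;
    }
  }
  if (kept == 0) stop("iters must exceed burnin");
  freq /= kept;
  bhat /= kept;
  return List::create(
    _["model_freq"] = freq,
    _["effects"] = bhat,
    _["mu"] = mu_hat / kept,
    _["pi_null"] = pi_hat / kept,
    _["sigma2_b"] = sigb_hat / kept,
    _["sigma2_e"] = sige_hat / kept,
    _["kept"] = kept);
}
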