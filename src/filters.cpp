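#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial filter kernels. These are the hot inner loops of MAP
// fitting and the recovery harnesses; the exported R wrappers add tibble
// packaging and validation. All predictions (muhat) are the one-step-ahead
// quantities computed before the trial's input is absorbed.

static inline double sgm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export(name = ".rw_filter_c")]]
List rw_filter_c(NumericVector u, double v0, double alpha) {
  int K = u.size();
  NumericVector muhat(K), delta(K), v(K);
  double val = v0;
  for (int k = 0; k < K; ++k) {
    muhat[k] = val;
    delta[k] = u[k] - val;
    val += alpha * delta[k];
    v[k] = val;
  }
  return List::create(_["muhat_1"] = muhat, _["delta_1"] = delta,
                      _["value"] = v);
}

// [[Rcpp::export(name = ".sk1_filter_c")]]
List sk1_filter_c(NumericVector u, double v0, double alpha0, double eta) {
  int K = u.size();
  NumericVector muhat(K), delta(K), v(K), a(K);
  double val = v0, gain = alpha0;
  for (int k = 0; k < K; ++k) {
    muhat[k] = val;
    delta[k] = u[k] - val;
    val += gain * delta[k];
    gain += eta * (std::fabs(delta[k]) - gain);
    if (gain < 0.0) gain = 0.0;
    if (gain > 1.0) gain = 1.0;
    v[k] = val;
    a[k] = gain;
  }
  return List::create(_["muhat_1"] = muhat, _["delta_1"] = delta,
                      _["value"] = v, _["alpha_k"] = a);
}

// Binary hierarchical Gaussian filter with n_levels in {2, 3, 4}.
// Level 1 is the binary outcome; levels 2..n are Gaussian. omega is the
// tonic volatility of every intermediate level (level 2, and level 3 when
// n = 4); the top level's variance increment is exp(theta) for n >= 3 and
// exp(omega) for n = 2. kappa couples each level to the one above.
// mu0/sigma0 hold starting values for levels 2..n (length n - 1).
// Returns -1 in `bad_trial` when all variances stayed positive; otherwise
// the 1-based trial and `bad_level` where a posterior variance failed.
// [[Rcpp::export(name = ".hgf_filter_c")]]
List hgf_filter_c(NumericVector u, int n_levels, double omega, double theta,
                  double kappa, NumericVector mu0, NumericVector sigma0) {
  int K = u.size();
  int n = n_levels;            // total levels incl. binary level 1
  int m = n - 1;               // number of Gaussian levels
  NumericMatrix mu(K, m), sigma(K, m), muhat(K, m), pihat(K, m), da(K, m);
  NumericVector muhat1(K), delta1(K);
  std::vector<double> cmu(m), csa(m);
  for (int i = 0; i < m; ++i) { cmu[i] = mu0[i]; csa[i] = sigma0[i]; }
  int bad_trial = -1, bad_level = -1;

  // volatility increment of Gaussian level j (0-based within Gaussians):
  // exp(kappa * mu_above + om_j) with om_j = omega below the top and the
  // top increment a constant (theta, or omega when the top is level 2)
  for (int k = 0; k < K; ++k) {
    // --- predictions (top-down), from previous means
    std::vector<double> mh(m), ph(m), vinc(m);
    for (int j = m - 1; j >= 0; --j) {
      mh[j] = cmu[j];
      if (j == m - 1) {
        vinc[j] = std::exp(n == 2 ? omega : theta);
      } else {
        vinc[j] = std::exp(kappa * cmu[j + 1] + omega);
      }
      ph[j] = 1.0 / (csa[j] + vinc[j]);
    }
    double mh1 = sgm(kappa * mh[0]);
    muhat1[k] = mh1;
    double d1 = u[k] - mh1;
    delta1[k] = d1;

    // --- level-2 update: Bernoulli information muhat1 (1 - muhat1)
    double pi2 = ph[0] + kappa * kappa * mh1 * (1.0 - mh1);
    double mu2 = mh[0] + kappa / pi2 * d1;
    double sa2 = 1.0 / pi2;
    if (!(sa2 > 0.0) || !std::isfinite(sa2)) { bad_trial = k + 1; bad_level = 2; break; }
    double da2 = (sa2 + (mu2 - mh[0]) * (mu2 - mh[0])) * ph[0] - 1.0;
    cmu[0] = mu2; csa[0] = sa2; da(k, 0) = da2;

    // --- volatility levels 3..n: precision-weighted volatility updates
    for (int j = 1; j < m; ++j) {
      double v = vinc[j - 1];            // exp(kappa mu_j+... ) of child
      double w = v * ph[j - 1];
      double dachild = da(k, j - 1);
      double pij = ph[j] + 0.5 * kappa * kappa * w * (w + (2.0 * w - 1.0) * dachild);
      double muj = mh[j] + 0.5 * (1.0 / pij) * kappa * w * dachild;
      double saj = 1.0 / pij;
      if (!(saj > 0.0) || !std::isfinite(saj)) { bad_trial = k + 1; bad_level = j + 2; break; }
      da(k, j) = (saj + (muj - mh[j]) * (muj - mh[j])) * ph[j] - 1.0;
      cmu[j] = muj; csa[j] = saj;
    }
    if (bad_trial > 0) break;

    for (int j = 0; j < m; ++j) {
      mu(k, j) = cmu[j]; sigma(k, j) = csa[j];
      muhat(k, j) = mh[j]; pihat(k, j) = ph[j];
    }
  }

  return List::create(_["muhat_1"] = muhat1, _["delta_1"] = delta1,
                      _["mu"] = mu, _["sigma"] = sigma, _["muhat"] = muhat,
                      _["pihat"] = pihat, _["da"] = da,
                      _["bad_trial"] = bad_trial, _["bad_level"] = bad_level);
}
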