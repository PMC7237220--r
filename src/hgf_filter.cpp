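#include <Rcpp.h>
using namespace Rcpp;

// Sequential two-level HGF for continuous inputs.
//
// Per trial k (rho = 0, t = 1):
//   mu1hat = mu1[k-1]
//   pi1hat = 1 / (1/pi1[k-1] + exp(kappa*mu2[k-1] + omega1))
//   delta_u = u[k] - mu1hat
//   pi1 = pi1hat + pi_u
//   mu1 = mu1hat + (pi_u / pi1) * delta_u
//   delta1 = (1/pi1 + (mu1 - mu1hat)^2) * pi1hat - 1   (variance-normalized)
//   w1 = exp(kappa*mu2[k-1] + omega1) * pi1hat
//   pi2hat = 1 / (1/pi2[k-1] + exp(omega2))
//   pi2 = pi2hat + 0.5*kappa^2*w1*(w1 + (2*w1 - 1)*delta1)
//   mu2 = mu2hat + 0.5*(1/pi2)*kappa*w1*delta1
//
// Any non-positive or non-finite precision marks the trajectory invalid at
// that trial ("bad" = 1-based trial index, 0 when the whole series is valid);
// the caller decides whether to raise or to reject the parameter proposal.

// [[Rcpp::export]]
List hgf_filter_core(NumericVector u, double kappa, double omega1,
                     double omega2, double pi_u, double mu1_0, double sigma1_0,
                     double mu2_0, double sigma2_0) {
  const int n = u.size();
  NumericVector mu1hat(n, NA_REAL), mu1(n, NA_REAL), pi1hat(n, NA_REAL),
      pi1(n, NA_REAL), mu2hat(n, NA_REAL), mu2(n, NA_REAL), pi2hat(n, NA_REAL),
      pi2(n, NA_REAL), delta_u(n, NA_REAL), delta1(n, NA_REAL),
      eps1(n, NA_REAL), eps2(n, NA_REAL), w1(n, NA_REAL);
  double mu1p = mu1_0, pi1p = 1.0 / sigma1_0;
  double mu2p = mu2_0, pi2p = 1.0 / sigma2_0;
  const double theta = std::exp(omega2);
  int bad = 0;
  if (!(pi1p > 0.0) || !(pi2p > 0.0) || !std::isfinite(theta)) bad = 1;
  for (int k = 0; k < n && bad == 0; ++k) {
    const double ex = std::exp(kappa * mu2p + omega1);
    mu1hat[k] = mu1p;
    pi1hat[k] = 1.0 / (1.0 / pi1p + ex);
    delta_u[k] = u[k] - mu1hat[k];
    pi1[k] = pi1hat[k] + pi_u;
    mu1[k] = mu1hat[k] + (pi_u / pi1[k]) * delta_u[k];
    eps1[k] = mu1[k] - mu1hat[k];
    delta1[k] = (1.0 / pi1[k] + eps1[k] * eps1[k]) * pi1hat[k] - 1.0;
    w1[k] = ex * pi1hat[k];
    mu2hat[k] = mu2p;
    pi2hat[k] = 1.0 / (1.0 / pi2p + theta);
    pi2[k] = pi2hat[k] +
             0.5 * kappa * kappa * w1[k] * (w1[k] + (2.0 * w1[k] - 1.0) * delta1[k]);
    const bool ok = std::isfinite(pi1hat[k]) && pi1hat[k] > 0.0 &&
                    std::isfinite(pi1[k]) && pi1[k] > 0.0 &&
                    std::isfinite(pi2hat[k]) && pi2hat[k] > 0.0 &&
                    std::isfinite(pi2[k]) && pi2[k] > 0.0 &&
                    std::isfinite(mu1[k]);
    if (!ok) {
      bad = k + 1;
      break;
    }
    mu2[k] = mu2hat[k] + 0.5 * (1.0 / pi2[k]) * kappa * w1[k] * delta1[k];
    eps2[k] = mu2[k] - mu2hat[k];
    if (!std::isfinite(mu2[k])) {
      bad = k + 1;
      break;
    }
    mu1p = mu1[k];
    pi1p = pi1[k];
    mu2p = mu2[k];
    pi2p = pi2[k];
  }
  return List::create(
      _["u"] = u, _["mu1hat"] = mu1hat, _["mu1"] = mu1, _["pi1hat"] = pi1hat,
      _["pi1"] = pi1, _["mu2hat"] = mu2hat, _["mu2"] = mu2,
      _["pi2hat"] = pi2hat, _["pi2"] = pi2, _["delta_u"] = delta_u,
      _["delta1"] = delta1, _["eps1"] = eps1, _["eps2"] = eps2, _["w1"] = w1,
      _["bad"] = bad);
}
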