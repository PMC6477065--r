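#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial cores for the three perceptual models. Each returns the
// full per-trial trajectory plus an `ok` flag; parameter regimes that drive
// a precision non-positive (or non-finite) abort early with ok = false and
// the R wrappers raise a classed condition. Kept in C++ because MAP fitting
// and the recovery studies evaluate these filters hundreds of thousands of
// times.

// [[Rcpp::export]]
List hgf_filter_core(NumericVector u, double omega2, double omega3,
                     double kappa, double mu2_0, double sigma2_0,
                     double mu3_0, double sigma3_0) {
  const int n = u.size();
  NumericVector muhat1(n), mu2(n), sigma2(n), mu3(n), sigma3(n),
      pihat2(n), pihat3(n), delta1(n), delta2(n);
  double m2 = mu2_0, s2 = sigma2_0, m3 = mu3_0, s3 = sigma3_0;
  bool ok = true;
  int bad_trial = -1;
  for (int k = 0; k < n; ++k) {
    // predictions carried over from the previous posterior
    const double muhat2 = m2;
    const double muhat3 = m3;
    const double mh1 = 1.0 / (1.0 + std::exp(-muhat2));
    const double ph2 = 1.0 / (s2 + std::exp(kappa * muhat3 + omega2));
    const double ph3 = 1.0 / (s3 + std::exp(omega3));
    if (!(ph2 > 0.0) || !(ph3 > 0.0) ||
        !std::isfinite(ph2) || !std::isfinite(ph3)) {
      ok = false; bad_trial = k + 1; break;
    }
    // level-2 update driven by the outcome prediction error
    const double d1 = u[k] - mh1;
    const double p2 = ph2 + mh1 * (1.0 - mh1);
    const double m2_new = muhat2 + d1 / p2;
    const double s2_new = 1.0 / p2;
    // level-3 update driven by the volatility prediction error
    const double v2 = std::exp(kappa * muhat3 + omega2);
    const double w2 = v2 * ph2;
    const double d2 =
        (1.0 / p2 + (m2_new - muhat2) * (m2_new - muhat2)) * ph2 - 1.0;
    const double p3 =
        ph3 + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
    if (!(p3 > 0.0) || !std::isfinite(p3)) {
      ok = false; bad_trial = k + 1; break;
    }
    const double m3_new = muhat3 + (kappa / (2.0 * p3)) * w2 * d2;

    muhat1[k] = mh1;
    pihat2[k] = ph2;
    pihat3[k] = ph3;
    delta1[k] = d1;
    delta2[k] = d2;
    mu2[k] = m2_new;  sigma2[k] = s2_new;
    mu3[k] = m3_new;  sigma3[k] = 1.0 / p3;

    m2 = m2_new; s2 = s2_new;
    m3 = m3_new; s3 = 1.0 / p3;
  }
  return List::create(
      _["ok"] = ok, _["bad_trial"] = bad_trial,
      _["muhat1"] = muhat1, _["mu2"] = mu2, _["sigma2"] = sigma2,
      _["mu3"] = mu3, _["sigma3"] = sigma3,
      _["pihat2"] = pihat2, _["pihat3"] = pihat3,
      _["delta1"] = delta1, _["delta2"] = delta2);
}

// [[Rcpp::export]]
List rw_filter_core(NumericVector u, double alpha, double v0, double eps) {
  const int n = u.size();
  NumericVector muhat1(n), value(n), lr(n), delta1(n);
  double v = v0;
  for (int k = 0; k < n; ++k) {
    const double vhat = v;
    const double d = u[k] - vhat;
    v = vhat + alpha * d;
    muhat1[k] = std::min(std::max(vhat, eps), 1.0 - eps);
    value[k] = v;
    lr[k] = alpha;
    delta1[k] = d;
  }
  return List::create(_["ok"] = true, _["muhat1"] = muhat1,
                      _["value"] = value, _["lr"] = lr,
                      _["delta1"] = delta1);
}

// [[Rcpp::export]]
List sk1_filter_core(NumericVector u, double mu_meta, double beta0,
                     double v0, double alpha_cap, double eps) {
  const int n = u.size();
  NumericVector muhat1(n), value(n), lr(n), delta1(n), beta(n), hgain(n);
  double v = v0, b = beta0, h = 0.0;
  for (int k = 0; k < n; ++k) {
    const double vhat = v;
    const double d = u[k] - vhat;
    b = b + mu_meta * d * h;
    double a = std::exp(b);
    if (a > alpha_cap) a = alpha_cap;
    v = vhat + a * d;
    h = (h + a * d) * std::max(0.0, 1.0 - a);
    muhat1[k] = std::min(std::max(vhat, eps), 1.0 - eps);
    value[k] = v;
    lr[k] = a;
    delta1[k] = d;
    beta[k] = b;
    hgain[k] = h;
  }
  return List::create(_["ok"] = true, _["muhat1"] = muhat1,
                      _["value"] = value, _["lr"] = lr,
                      _["delta1"] = delta1, _["beta"] = beta,
                      _["h"] = hgain);
}
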