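#include <Rcpp.h>
using namespace Rcpp;

static inline double exp_clip(double x) {
  if (x > 36.0) x = 36.0;
  if (x < -36.0) x = -36.0;
  return std::exp(x);
}

// Combined binary HGF + Rescorla-Wagner filter over one session.
// Returns an n x 8 matrix: muhat1, sigmahat2, pblame, delta_b (NaN on
// correct trials), mu2, sigma2, mu3, sigma3. Beliefs in the first three
// columns are the pre-outcome predictions of each trial.
// [[Rcpp::export]]
NumericMatrix cudn_filter_cpp(IntegerVector outcome, IntegerVector wrong,
                              IntegerVector blame, double kappa, double omega,
                              double theta, double mu2_0, double mu3_0,
                              double sigma2_0, double sigma3_0, int levels,
                              double alpha, double p0) {
  int n = outcome.size();
  if (wrong.size() != n || blame.size() != n)
    stop("outcome, wrong and blame must have equal length");
  NumericMatrix out(n, 8);
  double mu2 = mu2_0, sigma2 = sigma2_0, mu3 = mu3_0, sigma3 = sigma3_0;
  double p = p0;
  for (int k = 0; k < n; ++k) {
    double muhat1 = 1.0 / (1.0 + std::exp(-mu2));
    double sigmahat2 = sigma2 + exp_clip(kappa * mu3 + omega);
    out(k, 0) = muhat1;
    out(k, 1) = sigmahat2;
    out(k, 2) = p;

    double da1 = outcome[k] - muhat1;
    double pihat2 = 1.0 / sigmahat2;
    double pi2 = pihat2 + muhat1 * (1.0 - muhat1);
    if (!(pi2 > 0.0) || !R_finite(pi2))
      stop("non-positive level-2 precision: parameter pathology");
    double mu2_new = mu2 + da1 / pi2;
    double sigma2_new = 1.0 / pi2;

    if (levels == 3) {
      double pihat3 = 1.0 / (sigma3 + theta);
      double w2 = exp_clip(kappa * mu3 + omega) * pihat2;
      double da2 = (sigma2_new + (mu2_new - mu2) * (mu2_new - mu2)) * pihat2 - 1.0;
      double pi3 = pihat3 + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * da2);
      if (!(pi3 > 0.0) || !R_finite(pi3))
        stop("non-positive level-3 precision: parameter pathology");
      mu3 = mu3 + 0.5 * kappa * w2 * da2 / pi3;
      sigma3 = 1.0 / pi3;
    }
    mu2 = mu2_new;
    sigma2 = sigma2_new;

    if (wrong[k] == 1) {
      double delta = blame[k] - p;
      out(k, 3) = delta;
      p += alpha * delta;
    } else {
      out(k, 3) = NA_REAL;
    }
    out(k, 4) = mu2;
    out(k, 5) = sigma2;
    out(k, 6) = mu3;
    out(k, 7) = sigma3;
  }
  return out;
}
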