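#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized squared-hinge linear SVM
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i (w'x_i + b))^2
// following the standard dual CD scheme (alpha in [0, inf), Qbar_ii adds
// 1/(2C)).  The bias is handled through an augmented constant feature of
// value `bias_scale`, so b = bias_scale * w_aug.  Iteration order is a
// seeded permutation per epoch; the seed makes the fit bit-reproducible
// and independent of R's RNG stream.
//
// [[Rcpp::export]]
List svm_dcd_fit(const NumericMatrix& X, const NumericVector& y,
                 double C, double tol, int max_iter,
                 double bias_scale, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (C <= 0) stop("C must be positive");

  const int pa = p + 1;                 // augmented dimension (bias)
  std::vector<double> w(pa, 0.0), alpha(n, 0.0), qii(n);
  const double diag = 1.0 / (2.0 * C);

  for (int i = 0; i < n; ++i) {
    double s = bias_scale * bias_scale;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s + diag;
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::mt19937 rng(static_cast<unsigned>(seed));

  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    std::shuffle(order.begin(), order.end(), rng);
    double max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      const int i = order[k];
      double wx = w[p] * bias_scale;
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      const double G = y[i] * wx - 1.0 + diag * alpha[i];
      // projected gradient for the constraint alpha_i >= 0
      double PG = G;
      if (alpha[i] == 0.0 && G > 0.0) PG = 0.0;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (PG != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        alpha[i] = a_new;
        const double d = (a_new - a_old) * y[i];
        for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
        w[p] += d * bias_scale;
      }
    }
    if (max_viol < tol) { converged = true; ++iter; break; }
  }

  NumericVector wv(p);
  for (int j = 0; j < p; ++j) wv[j] = w[j];
  return List::create(_["w"] = wv,
                      _["b"] = w[p] * bias_scale,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
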