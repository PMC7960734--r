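#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM
//
//   min_w  0.5 ||w||^2 + 0.5 (b/S)^2 + C * sum_i max(0, 1 - y_i (w.x_i + b))
//
// solved in the dual (0 <= alpha_i <= C) by randomized coordinate sweeps
// (Hsieh et al., ICML 2008). The bias is an augmented constant feature of
// value S = `bias_scale`, so it carries a weak penalty of its own — the
// standard fast-linear-SVM formulation.
//
// X: n x p feature matrix, y: +/-1 labels. Returns the weight vector of
// length p + 1 with the bias (already rescaled) last.
// [[Rcpp::export(name = ".svm_dcd")]]
List svm_dcd(NumericMatrix X, NumericVector y, double C,
             double eps = 1e-4, int max_sweeps = 2000,
             double bias_scale = 1.0, int seed = 1) {
  const int n = X.nrow(), p = X.ncol();
  const int pa = p + 1; // augmented width (bias feature last)

  // contiguous row-major copy: row i occupies xr[i*pa .. i*pa+pa-1]
  std::vector<double> xr(static_cast<size_t>(n) * pa);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xr[static_cast<size_t>(i) * pa + j] = X(i, j);
    xr[static_cast<size_t>(i) * pa + p] = bias_scale;
  }

  std::vector<double> w(pa, 0.0), alpha(n, 0.0), qdiag(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &xr[static_cast<size_t>(i) * pa];
    double s = 0.0;
    for (int j = 0; j < pa; ++j) s += xi[j] * xi[j];
    qdiag[i] = s;
  }

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::mt19937 rng(static_cast<unsigned int>(seed));

  int sweep = 0;
  for (; sweep < max_sweeps; ++sweep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      const int i = idx[k];
      const double* xi = &xr[static_cast<size_t>(i) * pa];
      double wx = 0.0;
      for (int j = 0; j < pa; ++j) wx += w[j] * xi[j];
      const double G = y[i] * wx - 1.0; // dual gradient

      double PG = G; // projected onto the box [0, C]
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::abs(PG) > max_viol) max_viol = std::abs(PG);

      if (PG != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qdiag[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double d = (a_new - a_old) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < pa; ++j) w[j] += d * xi[j];
        }
      }
    }
    if (max_viol < eps) { ++sweep; break; }
  }

  NumericVector wout(pa);
  for (int j = 0; j < p; ++j) wout[j] = w[j];
  wout[p] = w[p] * bias_scale; // decision uses s(x) = w.x + b
  return List::create(_["w"] = wout,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["sweeps"] = sweep);
}
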