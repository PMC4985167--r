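#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin kernel SVM dual
//   min 1/2 a'Qa - e'a   s.t. 0 <= a_i <= C_i, y'a = 0,  Q_ij = y_i y_j K_ij
// with per-sample box constraints C_i (per-class misclassification costs).
// Working-set selection: maximal violating pair. K is the precomputed
// kernel matrix of the training set.
//
// Returns alpha and the bias b of the decision function
//   f(x) = sum_i alpha_i y_i K(x_i, x) + b.
// [[Rcpp::export(rng = false)]]
List smo_solve(const NumericMatrix& K, const IntegerVector& y,
               const NumericVector& C, double tol = 1e-3,
               int max_iter = 200000) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient (Q alpha)_i - 1
  const double INF = std::numeric_limits<double>::infinity();
  bool converged = false;
  double m = 0.0, M = 0.0;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    m = -INF;
    M = INF;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] == 1) ? (alpha[t] < C[t]) : (alpha[t] > 0.0);
      const bool low = (y[t] == 1) ? (alpha[t] > 0.0) : (alpha[t] < C[t]);
      if (up && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) { converged = true; break; }
    double a = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (a <= 0.0) a = 1e-12;
    double d = (m - M) / a;
    // clip to the box along the feasible direction (y'a stays 0)
    const double lim_i = (y[i] == 1) ? (C[i] - alpha[i]) : alpha[i];
    const double lim_j = (y[j] == 1) ? alpha[j] : (C[j] - alpha[j]);
    if (d > lim_i) d = lim_i;
    if (d > lim_j) d = lim_j;
    alpha[i] += y[i] * d;
    alpha[j] -= y[j] * d;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * d * (K(t, i) - K(t, j));
  }
  // bias: average y_i G_i over free support vectors (for a free SV,
  // y_i G_i equals the offset rho); fall back to the violation midpoint.
  double rho = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    const double eps = 1e-8 * std::max(1.0, C[t]);
    if (alpha[t] > eps && alpha[t] < C[t] - eps) {
      rho += y[t] * G[t];
      ++nfree;
    }
  }
  if (nfree > 0) rho /= nfree;
  else rho = -(m + M) / 2.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = -rho,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}

// Squared Euclidean cross-distance matrix (rows of A vs rows of B).
// [[Rcpp::export(rng = false)]]
NumericMatrix cross_dist2(const NumericMatrix& A, const NumericMatrix& B) {
  const int na = A.nrow(), nb = B.nrow(), p = A.ncol();
  NumericMatrix D(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        const double d = A(i, k) - B(j, k);
        s += d * d;
      }
      D(i, j) = s;
    }
  }
  return D;
}
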