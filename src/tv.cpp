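#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Weighted anisotropic-boundary TV with backward differences:
//   R(V) = sum_ij w_ij * sqrt(dx_ij^2 + dy_ij^2 + eps^2),
// dx_ij = V(i,j) - V(i-1,j) (0 on the first row), dy analogous on columns.
// eps smooths the non-differentiable point; the analytic gradient below is
// the exact derivative of this smoothed objective.

static inline double dxat(const NumericMatrix& V, int i, int j) {
  return i > 0 ? V(i, j) - V(i - 1, j) : 0.0;
}
static inline double dyat(const NumericMatrix& V, int i, int j) {
  return j > 0 ? V(i, j) - V(i, j - 1) : 0.0;
}

// [[Rcpp::export]]
double cpp_tv_objective(NumericMatrix V, NumericMatrix W, double eps) {
  const int nr = V.nrow(), nc = V.ncol();
  if (W.nrow() != nr || W.ncol() != nc) stop("weight map shape mismatch");
  double acc = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double dx = dxat(V, i, j), dy = dyat(V, i, j);
      acc += W(i, j) * std::sqrt(dx * dx + dy * dy + eps * eps);
    }
  return acc;
}

// [[Rcpp::export]]
NumericMatrix cpp_tv_gradient(NumericMatrix V, NumericMatrix W, double eps) {
  const int nr = V.nrow(), nc = V.ncol();
  if (W.nrow() != nr || W.ncol() != nc) stop("weight map shape mismatch");
  NumericMatrix den(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double dx = dxat(V, i, j), dy = dyat(V, i, j);
      den(i, j) = std::sqrt(dx * dx + dy * dy + eps * eps);
    }
  NumericMatrix G(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double g = 0.0;
      if (den(i, j) > 0.0)
        g += W(i, j) * (dxat(V, i, j) + dyat(V, i, j)) / den(i, j);
      if (i + 1 < nr && den(i + 1, j) > 0.0)
        g -= W(i + 1, j) * dxat(V, i + 1, j) / den(i + 1, j);
      if (j + 1 < nc && den(i, j + 1) > 0.0)
        g -= W(i, j + 1) * dyat(V, i, j + 1) / den(i, j + 1);
      G(i, j) = g;
    }
  return G;
}
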