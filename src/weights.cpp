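#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// reflective (symmetric, edge-including) index: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Bin the slice into B intensity levels using the slice-global min/max,
// with reflective padding of `pad` on every side.  Flat slices map to bin 0.
static std::vector<int> binned_padded(const NumericMatrix& x, int pad, int B,
                                      int& W, int& H) {
  const int nr = x.nrow(), nc = x.ncol();
  double mn = R_PosInf, mx = R_NegInf;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = x(i, j);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
  const double range = mx - mn;
  W = nr + 2 * pad;
  H = nc + 2 * pad;
  std::vector<int> out((size_t)W * H);
  for (int j = 0; j < H; ++j) {
    int cj = reflect(j - pad, nc);
    for (int i = 0; i < W; ++i) {
      int ci = reflect(i - pad, nr);
      int b = 0;
      if (range > 0.0) {
        b = (int)((x(ci, cj) - mn) / range * B);
        if (b >= B) b = B - 1;
        if (b < 0) b = 0;
      }
      out[(size_t)j * W + i] = b;
    }
  }
  return out;
}

static std::vector<double> padded_values(const NumericMatrix& x, int pad,
                                         int& W, int& H) {
  const int nr = x.nrow(), nc = x.ncol();
  W = nr + 2 * pad;
  H = nc + 2 * pad;
  std::vector<double> out((size_t)W * H);
  for (int j = 0; j < H; ++j) {
    int cj = reflect(j - pad, nc);
    for (int i = 0; i < W; ++i)
      out[(size_t)j * W + i] = x(reflect(i - pad, nr), cj);
  }
  return out;
}

// Joint histogram at one centre (1-based indices), aggregating all
// displaced patches in the search window (null displacement excluded).
// [[Rcpp::export]]
List cpp_joint_histogram(NumericMatrix slice, int ci, int cj, int a, int s,
                         int B) {
  if (a < 1 || s < a || B < 2) stop("need a >= 1, search >= a, bins >= 2");
  const int pad = a + s;
  int W, H;
  std::vector<int> bin = binned_padded(slice, pad, B, W, H);
  NumericMatrix counts(B, B);
  const int r = ci - 1 + pad, c = cj - 1 + pad;  // centre in padded coords
  double n = 0.0;
  for (int dsj = -s; dsj <= s; ++dsj) {
    for (int dsi = -s; dsi <= s; ++dsi) {
      if (dsi == 0 && dsj == 0) continue;
      for (int pj = -a; pj <= a; ++pj) {
        for (int pi = -a; pi <= a; ++pi) {
          int ia = bin[(size_t)(c + pj) * W + (r + pi)];
          int ib = bin[(size_t)(c + pj + dsj) * W + (r + pi + dsi)];
          counts(ia, ib) += 1.0;
          n += 1.0;
        }
      }
    }
  }
  return List::create(_["counts"] = counts, _["n"] = n);
}

// Per-pixel MI-based statistical measure M = MI(I_A, I_B over the search
// set) / H(I_A), clamped to [0, 1]; featureless stationary patches
// (H_A ~ 0) map to 0 (pure-smoothing state).  One aggregated joint
// histogram per pixel over all non-null displacements.
// [[Rcpp::export]]
NumericMatrix cpp_mi_measure_map(NumericMatrix slice, int a, int s, int B) {
  if (a < 1 || s < a || B < 2) stop("need a >= 1, search >= a, bins >= 2");
  const int nr = slice.nrow(), nc = slice.ncol();
  const int pad = a + s;
  int W, H;
  std::vector<int> bin = binned_padded(slice, pad, B, W, H);
  NumericMatrix M(nr, nc);

  std::vector<double> joint((size_t)B * B, 0.0);
  std::vector<int> touched;
  touched.reserve((size_t)(2 * a + 1) * (2 * a + 1) *
                  ((2 * s + 1) * (2 * s + 1) - 1));
  std::vector<double> marg_a(B), marg_b(B);
  const double log2e = 1.0 / std::log(2.0);

  for (int jc = 0; jc < nc; ++jc) {
    for (int ir = 0; ir < nr; ++ir) {
      const int r = ir + pad, c = jc + pad;
      touched.clear();
      for (int dsj = -s; dsj <= s; ++dsj) {
        for (int dsi = -s; dsi <= s; ++dsi) {
          if (dsi == 0 && dsj == 0) continue;
          for (int pj = -a; pj <= a; ++pj) {
            const int* rowa = &bin[(size_t)(c + pj) * W + r];
            const int* rowb = &bin[(size_t)(c + pj + dsj) * W + r + dsi];
            for (int pi = -a; pi <= a; ++pi) {
              int idx = rowa[pi] * B + rowb[pi];
              if (joint[idx] == 0.0) touched.push_back(idx);
              joint[idx] += 1.0;
            }
          }
        }
      }
      double n = 0.0;
      std::fill(marg_a.begin(), marg_a.end(), 0.0);
      std::fill(marg_b.begin(), marg_b.end(), 0.0);
      double hab = 0.0;
      for (size_t t = 0; t < touched.size(); ++t) {
        double cnt = joint[touched[t]];
        n += cnt;
        marg_a[touched[t] / B] += cnt;
        marg_b[touched[t] % B] += cnt;
      }
      for (size_t t = 0; t < touched.size(); ++t) {
        double p = joint[touched[t]] / n;
        hab -= p * std::log(p) * log2e;
        joint[touched[t]] = 0.0;  // reset for next centre
      }
      double ha = 0.0, hb = 0.0;
      for (int b = 0; b < B; ++b) {
        if (marg_a[b] > 0.0) {
          double p = marg_a[b] / n;
          ha -= p * std::log(p) * log2e;
        }
        if (marg_b[b] > 0.0) {
          double p = marg_b[b] / n;
          hb -= p * std::log(p) * log2e;
        }
      }
      double mi = ha + hb - hab;
      if (mi < 0.0) mi = 0.0;
      double m = (ha < 1e-12) ? 0.0 : mi / ha;
      if (m < 0.0) m = 0.0;
      if (m > 1.0) m = 1.0;
      M(ir, jc) = m;
    }
  }
  return M;
}

// Per-pixel non-local-means similarity: mean over non-null displacements of
// exp(-||patch_0 - patch_d||^2 / ((2a+1)^2 h^2)).
// [[Rcpp::export]]
NumericMatrix cpp_nlm_measure_map(NumericMatrix slice, int a, int s,
                                  double h) {
  if (a < 1 || s < a || h <= 0) stop("need a >= 1, search >= a, h > 0");
  const int nr = slice.nrow(), nc = slice.ncol();
  const int pad = a + s;
  int W, H;
  std::vector<double> val = padded_values(slice, pad, W, H);
  NumericMatrix M(nr, nc);
  const double np = (double)(2 * a + 1) * (2 * a + 1);
  const double denom = np * h * h;
  const int ndisp = (2 * s + 1) * (2 * s + 1) - 1;

  for (int jc = 0; jc < nc; ++jc) {
    for (int ir = 0; ir < nr; ++ir) {
      const int r = ir + pad, c = jc + pad;
      double acc = 0.0;
      for (int dsj = -s; dsj <= s; ++dsj) {
        for (int dsi = -s; dsi <= s; ++dsi) {
          if (dsi == 0 && dsj == 0) continue;
          double ssd = 0.0;
          for (int pj = -a; pj <= a; ++pj) {
            const double* rowa = &val[(size_t)(c + pj) * W + r];
            const double* rowb = &val[(size_t)(c + pj + dsj) * W + r + dsi];
            for (int pi = -a; pi <= a; ++pi) {
              double d = rowa[pi] - rowb[pi];
              ssd += d * d;
            }
          }
          acc += std::exp(-ssd / denom);
        }
      }
      M(ir, jc) = acc / ndisp;
    }
  }
  return M;
}
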