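// Median-based plate normalization kernels.
//
// Colony grids are small (32 x 48) but the polish iterates to its fixed
// point on every plate of every screen, and the spatial filter evaluates
// a windowed median per position, so these inner loops are compiled.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// median of the first n entries of buf (n >= 1), buf is scratch
static double med_inplace(std::vector<double>& buf, int n) {
  int half = n / 2;
  std::nth_element(buf.begin(), buf.begin() + half, buf.begin() + n);
  double hi = buf[half];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + half);
  return (lo + hi) / 2.0;
}

// [[Rcpp::export(name = ".polish_medians_cpp")]]
NumericMatrix polish_medians_cpp(NumericMatrix M_, double tol, int max_iter) {
  NumericMatrix M = clone(M_);
  int nr = M.nrow(), nc = M.ncol();
  std::vector<double> buf(nr * nc);
  for (int it = 0; it < max_iter; ++it) {
    double worst = 0.0;
    // global median
    int n = 0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        if (!NumericMatrix::is_na(M(i, j))) buf[n++] = M(i, j);
    if (n > 0) {
      double g = med_inplace(buf, n);
      if (std::abs(g) > worst) worst = std::abs(g);
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i)
          if (!NumericMatrix::is_na(M(i, j))) M(i, j) -= g;
    }
    // row medians
    for (int i = 0; i < nr; ++i) {
      n = 0;
      for (int j = 0; j < nc; ++j)
        if (!NumericMatrix::is_na(M(i, j))) buf[n++] = M(i, j);
      if (n == 0) continue;
      double m = med_inplace(buf, n);
      if (std::abs(m) > worst) worst = std::abs(m);
      for (int j = 0; j < nc; ++j)
        if (!NumericMatrix::is_na(M(i, j))) M(i, j) -= m;
    }
    // column medians
    for (int j = 0; j < nc; ++j) {
      n = 0;
      for (int i = 0; i < nr; ++i)
        if (!NumericMatrix::is_na(M(i, j))) buf[n++] = M(i, j);
      if (n == 0) continue;
      double m = med_inplace(buf, n);
      if (std::abs(m) > worst) worst = std::abs(m);
      for (int i = 0; i < nr; ++i)
        if (!NumericMatrix::is_na(M(i, j))) M(i, j) -= m;
    }
    if (worst < tol) break;
  }
  return M;
}

// [[Rcpp::export(name = ".moving_median_2d_cpp")]]
NumericMatrix moving_median_2d_cpp(NumericMatrix M, int h, bool exclude_block) {
  int nr = M.nrow(), nc = M.ncol();
  NumericMatrix S(nr, nc);
  std::vector<double> buf((2 * h + 1) * (2 * h + 1));
  for (int i = 0; i < nr; ++i) {
    int r0 = std::max(0, i - h), r1 = std::min(nr - 1, i + h);
    // rows of the 2x2 quadruplicate block this row belongs to (0-based)
    int br0 = (i / 2) * 2, br1 = br0 + 1;
    for (int j = 0; j < nc; ++j) {
      int c0 = std::max(0, j - h), c1 = std::min(nc - 1, j + h);
      int bc0 = (j / 2) * 2, bc1 = bc0 + 1;
      int n = 0;
      for (int jj = c0; jj <= c1; ++jj) {
        for (int ii = r0; ii <= r1; ++ii) {
          if (exclude_block && ii >= br0 && ii <= br1 && jj >= bc0 && jj <= bc1)
            continue;
          double v = M(ii, jj);
          if (!NumericMatrix::is_na(v)) buf[n++] = v;
        }
      }
      S(i, j) = (n > 0) ? med_inplace(buf, n) : 0.0;
    }
  }
  return S;
}
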