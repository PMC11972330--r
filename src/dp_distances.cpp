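#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Row-wise dynamic-programming distances between two sets of equal-length
// series. X and Y are genes x T matrices of the scaled WT and KO series;
// each function returns one value per row. T is small (typically 7), so the
// O(T^2) tables are allocated once and reused.

static double dtw_row(const double* x, const double* y, int n,
                      std::vector<double>& D) {
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double c = std::fabs(x[i] - y[j]);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else if (i == 0) best = D[j - 1];
      else if (j == 0) best = D[(i - 1) * n];
      else {
        best = D[(i - 1) * n + (j - 1)];
        double up = D[(i - 1) * n + j];
        double lf = D[i * n + (j - 1)];
        if (up < best) best = up;
        if (lf < best) best = lf;
      }
      D[i * n + j] = c + best;
    }
  }
  return D[n * n - 1];
}

// [[Rcpp::export]]
NumericVector cpp_dtw(NumericMatrix X, NumericMatrix Y) {
  int nr = X.nrow(), n = X.ncol();
  if (Y.nrow() != nr || Y.ncol() != n) stop("dimension mismatch");
  NumericVector out(nr);
  std::vector<double> D(n * n), x(n), y(n);
  for (int g = 0; g < nr; ++g) {
    for (int k = 0; k < n; ++k) { x[k] = X(g, k); y[k] = Y(g, k); }
    out[g] = dtw_row(x.data(), y.data(), n, D);
  }
  return out;
}

// Time-alignment measurement from the optimal DTW path. Backtracking from
// (T, T) prefers, on cost ties, the diagonal predecessor, then the
// horizontal one (j - 1), then the vertical one. With p path steps of which
// n_d are diagonal, n_h horizontal and n_v vertical:
//   TAM = n_h / p + n_v / p + (1 - n_d / p)   in [0, 2].
// [[Rcpp::export]]
NumericVector cpp_tam(NumericMatrix X, NumericMatrix Y) {
  int nr = X.nrow(), n = X.ncol();
  if (Y.nrow() != nr || Y.ncol() != n) stop("dimension mismatch");
  NumericVector out(nr);
  std::vector<double> D(n * n), x(n), y(n);
  for (int g = 0; g < nr; ++g) {
    for (int k = 0; k < n; ++k) { x[k] = X(g, k); y[k] = Y(g, k); }
    dtw_row(x.data(), y.data(), n, D);
    int i = n - 1, j = n - 1;
    long nd = 0, nh = 0, nv = 0;
    while (i > 0 || j > 0) {
      if (i == 0) { --j; ++nh; continue; }
      if (j == 0) { --i; ++nv; continue; }
      double dg = D[(i - 1) * n + (j - 1)];
      double lf = D[i * n + (j - 1)];
      double up = D[(i - 1) * n + j];
      double best = std::min(dg, std::min(lf, up));
      if (dg == best)      { --i; --j; ++nd; }
      else if (lf == best) { --j; ++nh; }
      else                 { --i; ++nv; }
    }
    double p = static_cast<double>(nd + nh + nv);
    out[g] = (p == 0.0) ? 0.0 : (nh / p + nv / p + (1.0 - nd / p));
  }
  return out;
}

// Discrete Frechet distance (Eiter-Mannila recursion):
//   D(i, j) = max(c(i, j), min(D(i-1, j), D(i, j-1), D(i-1, j-1)))
// with ground cost |x_i - y_j| on values alone, or the Euclidean distance in
// the (time, value) plane when a time vector is supplied.
// [[Rcpp::export]]
NumericVector cpp_frechet(NumericMatrix X, NumericMatrix Y,
                          Nullable<NumericVector> time = R_NilValue) {
  int nr = X.nrow(), n = X.ncol();
  if (Y.nrow() != nr || Y.ncol() != n) stop("dimension mismatch");
  bool use_time = time.isNotNull();
  NumericVector tv;
  if (use_time) {
    tv = time.get();
    if (tv.size() != n) stop("time vector length mismatch");
  }
  NumericVector out(nr);
  std::vector<double> D(n * n), x(n), y(n);
  for (int g = 0; g < nr; ++g) {
    for (int k = 0; k < n; ++k) { x[k] = X(g, k); y[k] = Y(g, k); }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        double c;
        if (use_time) {
          double dt = tv[i] - tv[j], dv = x[i] - y[j];
          c = std::sqrt(dt * dt + dv * dv);
        } else {
          c = std::fabs(x[i] - y[j]);
        }
        double prev;
        if (i == 0 && j == 0) prev = 0.0;
        else if (i == 0) prev = D[j - 1];
        else if (j == 0) prev = D[(i - 1) * n];
        else {
          prev = D[(i - 1) * n + (j - 1)];
          double up = D[(i - 1) * n + j];
          double lf = D[i * n + (j - 1)];
          if (up < prev) prev = up;
          if (lf < prev) prev = lf;
        }
        D[i * n + j] = std::max(c, prev);
      }
    }
    out[g] = D[n * n - 1];
  }
  return out;
}
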