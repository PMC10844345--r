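#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Average ranks of x[0..n-1] into r; returns the tie correction term
// T = sum over tie groups of (t^3 - t) for this judge.
static double average_ranks(const double* x, int n, double* r,
                            std::vector<int>& idx) {
  idx.resize(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double tcorr = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;  // average of ranks i+1..j+1
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    double t = j - i + 1;
    if (t > 1) tcorr += t * t * t - t;
    i = j + 1;
  }
  return tcorr;
}

// Tie-corrected Kendall's coefficient of concordance for a k x n matrix
// (rows = judges/windows, columns = items/targets). Returns NaN when the
// denominator vanishes (all items tied within every judge).
static double kendall_w_core(const double* m, int k, int n) {
  std::vector<double> rsum(n, 0.0), rank(n);
  std::vector<double> row(n);
  std::vector<int> idx;
  double tsum = 0.0;
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < n; ++i) row[i] = m[j + (R_xlen_t)k * i];
    tsum += average_ranks(row.data(), n, rank.data(), idx);
    for (int i = 0; i < n; ++i) rsum[i] += rank[i];
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += rsum[i] * rsum[i];
  double kk = (double)k, nn = (double)n;
  double num = 12.0 * s - 3.0 * kk * kk * nn * (nn + 1.0) * (nn + 1.0);
  double den = kk * kk * nn * (nn * nn - 1.0) - kk * tsum;
  if (den <= 0.0) return R_NaN;
  double w = num / den;
  if (w < 0.0) w = 0.0;
  if (w > 1.0) w = 1.0;
  return w;
}

// [[Rcpp::export]]
double cpp_kendall_w(NumericMatrix m) {
  return kendall_w_core(REAL(m), m.nrow(), m.ncol());
}

// Drop columns containing any non-finite entry, then compute W.
// Returns NaN if fewer than 2 usable columns remain.
static double kendall_w_dropna(const double* m, int k, int n,
                               std::vector<double>& buf, int* n_dropped) {
  std::vector<int> keep;
  keep.reserve(n);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (int j = 0; j < k; ++j)
      if (!R_finite(m[j + (R_xlen_t)k * i])) { ok = false; break; }
    if (ok) keep.push_back(i);
  }
  if (n_dropped) *n_dropped = n - (int)keep.size();
  int nk = (int)keep.size();
  if (nk < 2) return R_NaN;
  buf.resize((R_xlen_t)k * nk);
  for (int i = 0; i < nk; ++i)
    for (int j = 0; j < k; ++j)
      buf[j + (R_xlen_t)k * i] = m[j + (R_xlen_t)k * keep[i]];
  return kendall_w_core(buf.data(), k, nk);
}

// Per-seed concordance from a stack array (windows x targets x seeds).
// [[Rcpp::export]]
NumericVector cpp_kendall_w_stacks(NumericVector arr, int k, int n, int m) {
  NumericVector out(m);
  std::vector<double> buf;
  const double* p = REAL(arr);
  for (int s = 0; s < m; ++s)
    out[s] = kendall_w_dropna(p + (R_xlen_t)k * n * s, k, n, buf, nullptr);
  return out;
}

// Vertex-by-vertex stability from per-window correlation matrices.
// cor_arr has dim (V, V, W); entry (t, s, w) is the window-w correlation
// between target t and seed s. For each masked seed the stack is
// windows x (other masked vertices); targets with any non-finite
// correlation are dropped from every window's ranking for that seed.
// [[Rcpp::export]]
List cpp_stability_vv(NumericVector cor_arr, int V, int W,
                      IntegerVector mask_idx0) {
  int nm = mask_idx0.size();
  NumericVector out(V, NA_REAL);
  IntegerVector dropped(V, NA_INTEGER);
  const double* C = REAL(cor_arr);
  std::vector<double> stack((R_xlen_t)W * (nm - 1)), buf;
  for (int si = 0; si < nm; ++si) {
    int s = mask_idx0[si];
    int col = 0;
    for (int ti = 0; ti < nm; ++ti) {
      int t = mask_idx0[ti];
      if (t == s) continue;
      for (int w = 0; w < W; ++w)
        stack[w + (R_xlen_t)W * col] =
            C[t + (R_xlen_t)V * s + (R_xlen_t)V * V * w];
      ++col;
    }
    int nd = 0;
    out[s] = kendall_w_dropna(stack.data(), W, col, buf, &nd);
    dropped[s] = nd;
  }
  return List::create(_["w"] = out, _["n_dropped"] = dropped);
}

// Exact two-sided permutation p-value for the Spearman correlation of two
// untied rank vectors: enumerates all n! orderings with next_permutation.
// [[Rcpp::export]]
double cpp_spearman_exact_p(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  std::vector<double> y(ry.begin(), ry.end());
  std::sort(y.begin(), y.end());
  // statistic: sum of products of ranks (monotone in rho for fixed margins)
  double obs = 0.0, mean_s = 0.0;
  for (int i = 0; i < n; ++i) obs += rx[i] * ry[i];
  double rbar = (n + 1.0) / 2.0;
  mean_s = n * rbar * rbar;
  double dev = std::fabs(obs - mean_s) - 1e-9;
  long count = 0, total = 0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[i] * y[i];
    if (std::fabs(s - mean_s) >= dev) ++count;
    ++total;
  } while (std::next_permutation(y.begin(), y.end()));
  return (double)count / (double)total;
}
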