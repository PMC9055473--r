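#include <Rcpp.h>
using namespace Rcpp;

// Squared-cost dynamic programming table for two series.
// Local cost (x - y)^2; steps (1,0), (0,1), (1,1); endpoints matched;
// no warping window. Returns the full (n+1) x (m+1) table so that the
// optimal path can be backtracked.
static NumericMatrix dtw_table(const NumericVector& a, const NumericVector& b) {
  const int n = a.size(), m = b.size();
  NumericMatrix D(n + 1, m + 1);
  const double inf = R_PosInf;
  for (int i = 0; i <= n; ++i) D(i, 0) = inf;
  for (int j = 0; j <= m; ++j) D(0, j) = inf;
  D(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = a[i - 1] - b[j - 1];
      double best = D(i - 1, j - 1);
      if (D(i - 1, j) < best) best = D(i - 1, j);
      if (D(i, j - 1) < best) best = D(i, j - 1);
      D(i, j) = d * d + best;
    }
  }
  return D;
}

// [[Rcpp::export]]
double cpp_dtw_sq(NumericVector a, NumericVector b) {
  if (a.size() == 0 || b.size() == 0)
    stop("dtw distance requires non-empty series");
  NumericMatrix D = dtw_table(a, b);
  return D(a.size(), b.size());
}

// Optimal warping path as a 2-column matrix of 1-based index pairs,
// ordered from (1,1) to (n,m). Ties broken diagonal-first (then the
// predecessor with smaller i), which keeps paths deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_dtw_path(NumericVector a, NumericVector b) {
  if (a.size() == 0 || b.size() == 0)
    stop("dtw path requires non-empty series");
  const int n = a.size(), m = b.size();
  NumericMatrix D = dtw_table(a, b);
  std::vector<int> pi, pj;
  int i = n, j = m;
  pi.push_back(i); pj.push_back(j);
  while (i > 1 || j > 1) {
    double diag = D(i - 1, j - 1), up = D(i - 1, j), left = D(i, j - 1);
    if (diag <= up && diag <= left) { --i; --j; }
    else if (up <= left)            { --i; }
    else                            { --j; }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return path;
}

// Squared DTW distances between every row of X and every row of C.
// [[Rcpp::export]]
NumericMatrix cpp_dtw_cross(NumericMatrix X, NumericMatrix C) {
  const int n = X.nrow(), k = C.nrow();
  NumericMatrix out(n, k);
  for (int i = 0; i < n; ++i) {
    NumericVector xi = X(i, _);
    for (int c = 0; c < k; ++c) {
      out(i, c) = cpp_dtw_sq(xi, C(c, _));
    }
  }
  return out;
}

// One DBA update: align every row of X to the current barycenter along
// its optimal warping path, then replace each barycenter coordinate by
// the mean of all series values aligned to it.
// [[Rcpp::export]]
NumericVector cpp_dba_update(NumericMatrix X, NumericVector bary) {
  const int n = X.nrow(), L = bary.size();
  NumericVector sum(L), cnt(L);
  for (int i = 0; i < n; ++i) {
    NumericVector xi = X(i, _);
    IntegerMatrix path = cpp_dtw_path(xi, bary);
    for (int p = 0; p < path.nrow(); ++p) {
      int xi_idx = path(p, 0) - 1;
      int b_idx  = path(p, 1) - 1;
      sum[b_idx] += xi[xi_idx];
      cnt[b_idx] += 1.0;
    }
  }
  NumericVector out(L);
  for (int j = 0; j < L; ++j)
    out[j] = cnt[j] > 0 ? sum[j] / cnt[j] : bary[j];
  return out;
}
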