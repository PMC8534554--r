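#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact k nearest neighbors by brute force, Euclidean metric.
// Ties broken by lower row index; self excluded.
// [[Rcpp::export(name = ".cpp_knn")]]
List cpp_knn(NumericMatrix X, int k) {
  const int m = X.nrow(), p = X.ncol();
  IntegerMatrix idx(m, k);
  NumericMatrix dst(m, k);
  std::vector<std::pair<double, int> > cand(m - 1);
  for (int i = 0; i < m; ++i) {
    int c = 0;
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int f = 0; f < p; ++f) {
        double d = X(i, f) - X(j, f);
        s += d * d;
      }
      cand[c++] = std::make_pair(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int q = 0; q < k; ++q) {
      idx(i, q) = cand[q].second + 1;  // 1-based for R
      dst(i, q) = std::sqrt(cand[q].first);
    }
  }
  return List::create(_["indices"] = idx, _["distances"] = dst);
}

// Number of unordered pairs with distance <= r, for each r in rs.
// [[Rcpp::export(name = ".cpp_count_pairs")]]
NumericVector cpp_count_pairs(NumericMatrix X, NumericVector rs) {
  const int m = X.nrow(), p = X.ncol(), nr = rs.size();
  std::vector<double> r2(nr);
  for (int q = 0; q < nr; ++q) r2[q] = rs[q] * rs[q];
  NumericVector counts(nr);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double s = 0.0;
      for (int f = 0; f < p; ++f) {
        double d = X(i, f) - X(j, f);
        s += d * d;
      }
      for (int q = 0; q < nr; ++q)
        if (s <= r2[q]) counts[q] += 1.0;
    }
  }
  return counts;
}

// Greedy duplicate filter: drop a row whose Chebyshev (max-abs) distance to
// some earlier kept row is <= tol. Returns 1-based indices of kept rows.
// [[Rcpp::export(name = ".cpp_dedup_rows")]]
IntegerVector cpp_dedup_rows(NumericMatrix X, double tol) {
  const int m = X.nrow(), p = X.ncol();
  std::vector<int> keep;
  keep.reserve(m);
  for (int i = 0; i < m; ++i) {
    bool dup = false;
    for (size_t q = 0; q < keep.size() && !dup; ++q) {
      int j = keep[q];
      double mx = 0.0;
      for (int f = 0; f < p; ++f) {
        double d = std::fabs(X(i, f) - X(j, f));
        if (d > mx) mx = d;
        if (mx > tol) break;
      }
      dup = (mx <= tol);
    }
    if (!dup) keep.push_back(i);
  }
  IntegerVector out(keep.size());
  for (size_t q = 0; q < keep.size(); ++q) out[q] = keep[q] + 1;
  return out;
}
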