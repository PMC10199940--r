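#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sample-entropy style template-match counts with Chebyshev distance.
// Templates of length m and their (m+1)-extensions are both indexed
// i = 0..T-m-1, so every counted m-template has an extension. Self-matches
// are excluded; pairs are counted in both orders (the ratio is unaffected).
// [[Rcpp::export]]
NumericVector qe_counts_cpp(NumericVector x, int m, double r) {
  const int T = x.size();
  const int n = T - m;
  double B = 0.0, A = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dmax = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dmax) dmax = d;
        if (dmax > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 2.0;
      double dext = std::fabs(x[i + m] - x[j + m]);
      if (dext <= r && dmax <= r) A += 2.0;
    }
  }
  return NumericVector::create(B, A);
}

// One O(T^2) pass producing match counts for every tolerance in rs (sorted
// ascending) at a fixed m: for each template pair the Chebyshev distances at
// lengths m and m+1 are binned against rs, then suffix sums give counts.
// [[Rcpp::export]]
NumericMatrix qe_grid_counts_cpp(NumericVector x, int m, NumericVector rs) {
  const int T = x.size();
  const int n = T - m;
  const int nr = rs.size();
  std::vector<double> histB(nr + 1, 0.0), histA(nr + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dm) dm = d;
      }
      double dm1 = std::max(dm, std::fabs(x[i + m] - x[j + m]));
      // first tolerance index with rs[idx] >= distance
      int bi = std::lower_bound(rs.begin(), rs.end(), dm) - rs.begin();
      int ai = std::lower_bound(rs.begin(), rs.end(), dm1) - rs.begin();
      histB[bi] += 2.0;
      histA[ai] += 2.0;
    }
  }
  NumericMatrix out(nr, 2);
  double cumB = 0.0, cumA = 0.0;
  for (int t = 0; t < nr; ++t) {
    cumB += histB[t];
    cumA += histA[t];
    out(t, 0) = cumB;
    out(t, 1) = cumA;
  }
  return out;
}

// Natural visibility graph edges. Nodes i < j are connected iff every
// intermediate point lies strictly below the chord, i.e. the slope from i to
// j strictly exceeds the running maximum slope from i to any intermediate
// point. Adjacent points are always connected. Returns a 2-column (from, to)
// matrix of 1-based node indices.
// [[Rcpp::export]]
IntegerMatrix visibility_edges_cpp(NumericVector x) {
  const int T = x.size();
  std::vector<int> from, to;
  from.reserve(4 * T);
  to.reserve(4 * T);
  for (int i = 0; i < T - 1; ++i) {
    from.push_back(i + 1);
    to.push_back(i + 2);
    double maxslope = -std::numeric_limits<double>::infinity();
    for (int j = i + 2; j < T; ++j) {
      double slope_prev = (x[j - 1] - x[i]) / double(j - 1 - i);
      if (slope_prev > maxslope) maxslope = slope_prev;
      double slope_ij = (x[j] - x[i]) / double(j - i);
      if (slope_ij > maxslope) {
        from.push_back(i + 1);
        to.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(from.size(), 2);
  for (size_t e = 0; e < from.size(); ++e) {
    out(e, 0) = from[e];
    out(e, 1) = to[e];
  }
  return out;
}
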