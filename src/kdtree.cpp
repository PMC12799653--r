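#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// KD-tree over the rows of X, stored as parallel node arrays. Leaves hold
// contiguous ranges of the row permutation `perm`. axis == -1 marks a leaf.
namespace {

struct KdBuilder {
  const NumericMatrix X;
  int leaf_size;
  std::vector<int> perm, axis, left, right, start, end;
  std::vector<double> cut;

  KdBuilder(NumericMatrix X_, int ls) : X(X_), leaf_size(ls) {
    perm.resize(X.nrow());
    for (int i = 0; i < X.nrow(); ++i) perm[i] = i;
  }

  int build(int lo, int hi) {
    int node = static_cast<int>(axis.size());
    axis.push_back(-1);
    cut.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    start.push_back(lo);
    end.push_back(hi);
    if (hi - lo <= leaf_size) return node;

    // split on the axis of largest spread; identical points stay a leaf
    int p = X.ncol(), best_ax = -1;
    double best_spread = 0.0;
    for (int d = 0; d < p; ++d) {
      double mn = X(perm[lo], d), mx = mn;
      for (int i = lo + 1; i < hi; ++i) {
        double v = X(perm[i], d);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx - mn > best_spread) {
        best_spread = mx - mn;
        best_ax = d;
      }
    }
    if (best_ax < 0) return node;

    int mid = (lo + hi) / 2;
    const NumericMatrix& XX = X;
    const int ax = best_ax;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&XX, ax](int a, int b) { return XX(a, ax) < XX(b, ax); });
    axis[node] = ax;
    cut[node] = X(perm[mid], ax);
    int lft = build(lo, mid);
    int rgt = build(mid, hi);
    left[node] = lft;
    right[node] = rgt;
    return node;
  }
};

// Squared distance from row `row` of X to q, accumulated in column order.
// This fixed order is shared with row_dists_cpp so that every distance in the
// package is computed with bit-identical arithmetic.
inline double row_sqdist(const NumericMatrix& X, int row, const NumericVector& q,
                         double stop_above) {
  double acc = 0.0;
  const int p = X.ncol();
  for (int j = 0; j < p; ++j) {
    double v = X(row, j) - q[j];
    acc += v * v;
    if (acc > stop_above) break;  // later terms are non-negative
  }
  return acc;
}

}  // namespace

// [[Rcpp::export]]
List kd_build_cpp(NumericMatrix X, int leaf_size) {
  if (leaf_size < 1) stop("leaf_size must be >= 1");
  KdBuilder b(X, leaf_size);
  b.build(0, X.nrow());
  return List::create(_["perm"] = wrap(b.perm), _["axis"] = wrap(b.axis),
                      _["cut"] = wrap(b.cut), _["left"] = wrap(b.left),
                      _["right"] = wrap(b.right), _["start"] = wrap(b.start),
                      _["end"] = wrap(b.end), _["leaf_size"] = leaf_size);
}

// All rows (0-based) with squared distance <= radius^2 from q.
// [[Rcpp::export]]
IntegerVector kd_query_cpp(List tree, NumericMatrix X, NumericVector q,
                           double radius) {
  IntegerVector perm = tree["perm"], axis = tree["axis"], left = tree["left"],
                right = tree["right"], start = tree["start"], end = tree["end"];
  NumericVector cut = tree["cut"];
  const double r2 = radius * radius;
  std::vector<int> hits;
  std::vector<int> stack;
  stack.push_back(0);
  while (!stack.empty()) {
    int node = stack.back();
    stack.pop_back();
    int ax = axis[node];
    if (ax < 0) {
      for (int i = start[node]; i < end[node]; ++i) {
        int row = perm[i];
        if (row_sqdist(X, row, q, r2) <= r2) hits.push_back(row);
      }
    } else {
      double diff = q[ax] - cut[node];
      if (diff <= radius) stack.push_back(left[node]);   // coords <= cut
      if (diff >= -radius) stack.push_back(right[node]); // coords >= cut
    }
  }
  std::sort(hits.begin(), hits.end());
  return wrap(hits);
}

// Euclidean distances from every row of X to q.
// [[Rcpp::export]]
NumericVector row_dists_cpp(NumericMatrix X, NumericVector q) {
  const int n = X.nrow();
  NumericVector out(n);
  const double inf = R_PosInf;
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(row_sqdist(X, i, q, inf));
  return out;
}

// Euclidean distances from the given rows (0-based) of X to q.
// [[Rcpp::export]]
NumericVector row_dists_idx_cpp(NumericMatrix X, NumericVector q,
                                IntegerVector rows0) {
  const int n = rows0.size();
  NumericVector out(n);
  const double inf = R_PosInf;
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(row_sqdist(X, rows0[i], q, inf));
  return out;
}
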