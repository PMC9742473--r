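// Histogram-based CART regression tree with best-first growth.
//
// Features are quantile-binned once per fit (<= 256 bins; exact when a
// feature has few distinct values), so split search per node is a single
// O(|rows|) histogram accumulation per candidate feature plus a 256-bin
// scan — no per-node sorting. Split thresholds are stored on the original
// scale (midpoints between adjacent occupied bin boundaries), so
// prediction needs no binning.
//
// One growth routine serves both boosting flavours and the forest:
// expanding leaves highest-gain-first until either a per-leaf depth cap
// (depth-wise, XGBoost-style) or a total leaf-count cap (leaf-wise,
// LightGBM-style) stops it reproduces the classical recursive tree when
// only the depth cap binds, because every positive-gain split within the
// cap is eventually taken.
//
// Randomness (per-node feature subsampling) comes from R's RNG so that
// set.seed() on the R side makes whole forests reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// Quantile-bin every column. Returns integer codes (0-based) and, per
// column, the ascending boundary values: code(x) = #{b : boundary_b < x},
// i.e. x <= boundary_b  <=>  code <= b.
// [[Rcpp::export(name = ".cpp_bin_matrix")]]
List cpp_bin_matrix(NumericMatrix X, int max_bins) {
  const int n = X.nrow(), p = X.ncol();
  IntegerMatrix codes(n, p);
  List bounds(p);
  std::vector<double> v(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) v[i] = X(i, j);
    std::vector<double> u(v);
    std::sort(u.begin(), u.end());
    u.erase(std::unique(u.begin(), u.end()), u.end());
    std::vector<double> b;
    if ((int)u.size() <= max_bins) {
      for (size_t t = 0; t + 1 < u.size(); ++t)
        b.push_back(0.5 * (u[t] + u[t + 1]));
    } else {
      for (int q = 1; q < max_bins; ++q) {
        size_t idx = (size_t)((double)q * u.size() / max_bins);
        if (idx >= u.size() - 1) idx = u.size() - 2;
        b.push_back(0.5 * (u[idx] + u[idx + 1]));
      }
      b.erase(std::unique(b.begin(), b.end()), b.end());
    }
    for (int i = 0; i < n; ++i) {
      int c = (int)(std::upper_bound(b.begin(), b.end(), X(i, j)) -
                    b.begin());
      // boundary_b < x gives upper_bound on strict less; x exactly on a
      // boundary must go left (x <= boundary), handled by upper_bound
      // since boundaries are midpoints never equal to data values —
      // except for repeated quantile edges, where upper_bound is safe.
      codes(i, j) = c;
    }
    bounds[j] = NumericVector(b.begin(), b.end());
  }
  return List::create(_["codes"] = codes, _["bounds"] = bounds);
}

struct SplitInfo {
  int feat = -1;
  int bin = -1;       // last bin going left
  double thr = 0.0;   // original-scale threshold
  double gain = 0.0;  // SSE reduction
};

struct Leaf {
  std::vector<int> rows;
  double sum = 0.0;
  int depth = 0;
  int node_id = -1;
  SplitInfo best;
};

static SplitInfo best_split(const IntegerMatrix& codes, const List& bounds,
                            const NumericVector& y,
                            const std::vector<int>& rows, int mtry,
                            int min_node, double node_sum) {
  SplitInfo out;
  const int p = codes.ncol();
  const int n = (int)rows.size();
  if (n < 2 * min_node) return out;

  // partial Fisher-Yates over feature indices using R's RNG
  static std::vector<int> feats;
  feats.resize(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  const int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  double cnt[257], sum[257];
  for (int jj = 0; jj < m; ++jj) {
    const int f = feats[jj];
    NumericVector b = bounds[f];
    const int nb = b.size() + 1;  // number of bins
    if (nb < 2) continue;
    std::fill(cnt, cnt + nb, 0.0);
    std::fill(sum, sum + nb, 0.0);
    for (int i : rows) {
      const int c = codes(i, f);
      cnt[c] += 1.0;
      sum[c] += y[i];
    }
    double lc = 0.0, ls = 0.0;
    for (int c = 0; c < nb - 1; ++c) {
      lc += cnt[c];
      ls += sum[c];
      if (lc < min_node) continue;
      const double rc = n - lc;
      if (rc < min_node) break;
      const double rs = node_sum - ls;
      const double gain = ls * ls / lc + rs * rs / rc -
        node_sum * node_sum / n;
      if (gain > out.gain + 1e-12) {
        out.gain = gain;
        out.feat = f;
        out.bin = c;
        out.thr = b[c];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_grow_tree")]]
List cpp_grow_tree(List binned, NumericVector y, IntegerVector rows,
                   int mtry, int max_depth, int max_leaves, int min_node) {
  IntegerMatrix codes = binned["codes"];
  List bounds = binned["bounds"];

  std::vector<int> feat, left, right;
  std::vector<double> thr, value;
  std::vector<double> gain_by_feat(codes.ncol(), 0.0);

  auto new_node = [&]() {
    feat.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return (int)feat.size() - 1;
  };

  Leaf root;
  root.rows.assign(rows.begin(), rows.end());
  for (int i : root.rows) root.sum += y[i];
  root.node_id = new_node();
  value[root.node_id] = root.rows.empty() ? 0.0
    : root.sum / root.rows.size();
  if (root.depth < max_depth)
    root.best = best_split(codes, bounds, y, root.rows, mtry, min_node,
                           root.sum);

  auto cmp = [](const Leaf& a, const Leaf& b) {
    return a.best.gain < b.best.gain;
  };
  std::priority_queue<Leaf, std::vector<Leaf>, decltype(cmp)> pq(cmp);
  if (root.best.feat >= 0) pq.push(std::move(root));

  int n_leaves = 1;
  while (!pq.empty() && n_leaves < max_leaves) {
    Leaf cur = pq.top();
    pq.pop();

    const int id = cur.node_id;
    feat[id] = cur.best.feat;
    thr[id] = cur.best.thr;
    gain_by_feat[cur.best.feat] += cur.best.gain;

    Leaf L, R;
    for (int i : cur.rows) {
      if (codes(i, cur.best.feat) <= cur.best.bin) {
        L.rows.push_back(i);
        L.sum += y[i];
      } else {
        R.rows.push_back(i);
      }
    }
    R.sum = cur.sum - L.sum;
    L.depth = R.depth = cur.depth + 1;
    L.node_id = new_node();
    R.node_id = new_node();
    left[id] = L.node_id;
    right[id] = R.node_id;
    value[L.node_id] = L.sum / L.rows.size();
    value[R.node_id] = R.sum / R.rows.size();
    ++n_leaves;

    if (L.depth < max_depth) {
      L.best = best_split(codes, bounds, y, L.rows, mtry, min_node, L.sum);
      if (L.best.feat >= 0) pq.push(std::move(L));
    }
    if (R.depth < max_depth) {
      R.best = best_split(codes, bounds, y, R.rows, mtry, min_node, R.sum);
      if (R.best.feat >= 0) pq.push(std::move(R));
    }
  }

  return List::create(_["feat"] = IntegerVector(feat.begin(), feat.end()),
                      _["thr"] = NumericVector(thr.begin(), thr.end()),
                      _["left"] = IntegerVector(left.begin(), left.end()),
                      _["right"] = IntegerVector(right.begin(), right.end()),
                      _["value"] = NumericVector(value.begin(), value.end()),
                      _["gain"] = NumericVector(gain_by_feat.begin(),
                                                gain_by_feat.end()));
}

// [[Rcpp::export(name = ".cpp_predict_tree")]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feat"], left = tree["left"],
    right = tree["right"];
  NumericVector thr = tree["thr"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feat[node] >= 0)
      node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_predict_forest")]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    NumericVector p = cpp_predict_tree(trees[b], X);
    for (int i = 0; i < n; ++i) out[i] += p[i];
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
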