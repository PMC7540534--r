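// Regression random forest (CART, variance-reduction splits) with
// bootstrap resampling and out-of-bag predictions.  Kept deliberately
// minimal: numeric features only (one-hot encoding happens in R), no
// surrogate splits, no importance.  Determinism: every tree draws from a
// private mt19937_64 seeded from (seed, tree index), so results do not
// depend on build order or platform RNG state.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // split: x <= threshold goes left
  int left, right;  // child node ids, -1 for leaf
  double value;     // mean response of node sample
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
  bool found = false;
};

// Best single-feature split of rows [begin,end) of idx by exhaustive scan.
SplitResult best_split(const NumericMatrix &X, const NumericVector &y,
                       std::vector<int> &idx, int begin, int end,
                       const std::vector<int> &features, int min_leaf,
                       std::vector<int> &scratch) {
  const int n = end - begin;
  double sum = 0.0;
  for (int i = begin; i < end; ++i) sum += y[idx[i]];
  const double parent_score = sum * sum / n;

  SplitResult best;
  for (int f : features) {
    scratch.assign(idx.begin() + begin, idx.begin() + end);
    std::sort(scratch.begin(), scratch.end(), [&](int a, int b) {
      double xa = X(a, f), xb = X(b, f);
      if (xa != xb) return xa < xb;
      return a < b; // deterministic tie-break
    });
    double left_sum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      left_sum += y[scratch[i]];
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf) continue;
      if (nr < min_leaf) break;
      const double xv = X(scratch[i], f), xnext = X(scratch[i + 1], f);
      if (xv == xnext) continue; // cannot split between equal values
      const double score = left_sum * left_sum / nl +
                           (sum - left_sum) * (sum - left_sum) / nr;
      const double gain = score - parent_score;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = f;
        best.threshold = xv + (xnext - xv) / 2.0;
        if (!(best.threshold > xv)) best.threshold = xv; // underflow guard
        best.found = true;
      }
    }
  }
  return best;
}

void grow(const NumericMatrix &X, const NumericVector &y,
          std::vector<int> &idx, int begin, int end, int node_id,
          std::vector<Node> &nodes, int mtry, int min_leaf,
          std::mt19937_64 &rng, std::vector<int> &feat_pool,
          std::vector<int> &scratch) {
  const int n = end - begin;
  double sum = 0.0;
  for (int i = begin; i < end; ++i) sum += y[idx[i]];
  nodes[node_id].value = sum / n;
  nodes[node_id].feature = -1;
  nodes[node_id].left = nodes[node_id].right = -1;

  if (n < 2 * min_leaf) return;
  bool constant = true;
  for (int i = begin + 1; i < end && constant; ++i)
    if (y[idx[i]] != y[idx[begin]]) constant = false;
  if (constant) return;

  // sample mtry candidate features without replacement (partial Fisher-Yates)
  const int p = (int)feat_pool.size();
  for (int i = 0; i < mtry; ++i) {
    std::uniform_int_distribution<int> pick(i, p - 1);
    std::swap(feat_pool[i], feat_pool[pick(rng)]);
  }
  std::vector<int> cand(feat_pool.begin(), feat_pool.begin() + mtry);

  SplitResult sp = best_split(X, y, idx, begin, end, cand, min_leaf, scratch);
  if (!sp.found) {
    // fall back to scanning all features so a relevant feature is never
    // starved by an unlucky mtry draw on an unsplittable candidate set
    std::vector<int> all(feat_pool.begin(), feat_pool.end());
    sp = best_split(X, y, idx, begin, end, all, min_leaf, scratch);
    if (!sp.found) return;
  }

  // partition idx[begin,end) around the split, stable
  std::vector<int> lo, hi;
  lo.reserve(n);
  hi.reserve(n);
  for (int i = begin; i < end; ++i) {
    if (X(idx[i], sp.feature) <= sp.threshold) lo.push_back(idx[i]);
    else hi.push_back(idx[i]);
  }
  std::copy(lo.begin(), lo.end(), idx.begin() + begin);
  std::copy(hi.begin(), hi.end(), idx.begin() + begin + (int)lo.size());

  const int mid = begin + (int)lo.size();
  const int left_id = (int)nodes.size();
  nodes.push_back(Node());
  const int right_id = (int)nodes.size();
  nodes.push_back(Node());
  nodes[node_id].feature = sp.feature;
  nodes[node_id].threshold = sp.threshold;
  nodes[node_id].left = left_id;
  nodes[node_id].right = right_id;

  grow(X, y, idx, begin, mid, left_id, nodes, mtry, min_leaf, rng, feat_pool,
       scratch);
  grow(X, y, idx, mid, end, right_id, nodes, mtry, min_leaf, rng, feat_pool,
       scratch);
}

double predict_one(const NumericMatrix &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

std::uint64_t tree_seed(double seed, int t) {
  // splitmix64 of (seed, t) so per-tree streams are independent
  std::uint64_t z = (std::uint64_t)seed * 0x9E3779B97F4A7C15ULL +
                    (std::uint64_t)(t + 1);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_leaf, double seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  if (min_leaf < 1) stop("min_leaf must be >= 1");
  if (ntree < 1) stop("ntree must be >= 1");

  List trees(ntree);
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_cnt(n, 0);

  std::vector<int> feat_pool(p), idx, scratch;
  for (int t = 0; t < ntree; ++t) {
    std::mt19937_64 rng(tree_seed(seed, t));
    for (int j = 0; j < p; ++j) feat_pool[j] = j;

    // bootstrap sample
    std::vector<char> inbag(n, 0);
    idx.assign(n, 0);
    std::uniform_int_distribution<int> draw(0, n - 1);
    for (int i = 0; i < n; ++i) {
      idx[i] = draw(rng);
      inbag[idx[i]] = 1;
    }

    std::vector<Node> nodes;
    nodes.push_back(Node());
    grow(X, y, idx, 0, n, 0, nodes, mtry, min_leaf, rng, feat_pool, scratch);

    NumericMatrix tree((int)nodes.size(), 5);
    for (int k = 0; k < (int)nodes.size(); ++k) {
      tree(k, 0) = nodes[k].feature;
      tree(k, 1) = nodes[k].threshold;
      tree(k, 2) = nodes[k].left;
      tree(k, 3) = nodes[k].right;
      tree(k, 4) = nodes[k].value;
    }
    trees[t] = tree;

    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_sum[i] += predict_one(tree, X, i);
        oob_cnt[i] += 1;
      }
    }
  }

  NumericVector oob(n);
  for (int i = 0; i < n; ++i)
    oob[i] = oob_cnt[i] > 0 ? oob_sum[i] / oob_cnt[i] : NA_REAL;

  return List::create(Named("trees") = trees, Named("oob") = oob,
                      Named("oob_n_trees") = oob_cnt);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
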