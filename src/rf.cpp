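// Random forest for binary classification: CART trees with gini impurity,
// bootstrap resampling, mtry features per node, grown to purity
// (min_node = 1), majority vote per tree. Scores returned to R are the
// fraction of trees voting positive. Own mt19937 stream so results are
// reproducible from a single integer seed independently of R's RNG.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;        // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  int pred = 0;         // leaf vote
};

struct TreeBuilder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int p, mtry, min_node;
  std::mt19937 &rng;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix &X_, const IntegerVector &y_, int mtry_,
              int min_node_, std::mt19937 &rng_)
      : X(X_), y(y_), p(X_.ncol()), mtry(mtry_), min_node(min_node_),
        rng(rng_) {}

  int build(std::vector<int> &idx, int lo, int hi) {
    int n = hi - lo;
    int pos = 0;
    for (int k = lo; k < hi; ++k) pos += y[idx[k]];
    int me = (int)nodes.size();
    nodes.push_back(Node());
    if (pos == 0 || pos == n || n <= min_node) {
      nodes[me].pred = (2 * pos >= n) ? 1 : 0;
      return me;
    }
    // sample mtry distinct features (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng)]);
    }
    double best_score = -1.0, best_thr = 0.0;
    int best_feat = -1;
    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      for (int k = 0; k < n; ++k) {
        int i = idx[lo + k];
        vals[k] = {X(i, f), y[i]};
      }
      std::sort(vals.begin(), vals.end());
      int lpos = 0;
      for (int k = 0; k < n - 1; ++k) {
        lpos += vals[k].second;
        if (vals[k + 1].first <= vals[k].first) continue;
        int ln = k + 1, rn = n - ln;
        int rpos = pos - lpos;
        // gini decrease up to constants: minimize weighted child gini
        double gl = (double)lpos * (ln - lpos) / ln;
        double gr = (double)rpos * (rn - rpos) / rn;
        double score = -(gl + gr);
        if (score > best_score) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_feat < 0) {   // all sampled features constant on this node
      nodes[me].pred = (2 * pos >= n) ? 1 : 0;
      return me;
    }
    // partition: simple stable two-pass
    std::vector<int> l, r;
    l.reserve(n); r.reserve(n);
    for (int k = lo; k < hi; ++k) {
      if (X(idx[k], best_feat) <= best_thr) l.push_back(idx[k]);
      else r.push_back(idx[k]);
    }
    if (l.empty() || r.empty()) {      // numerically degenerate split
      nodes[me].pred = (2 * pos >= n) ? 1 : 0;
      return me;
    }
    for (size_t k = 0; k < l.size(); ++k) idx[lo + k] = l[k];
    for (size_t k = 0; k < r.size(); ++k) idx[lo + l.size() + k] = r[k];
    nodes[me].feat = best_feat;
    nodes[me].thr = best_thr;
    int left = build(idx, lo, lo + (int)l.size());
    int right = build(idx, lo + (int)l.size(), hi);
    nodes[me].feat = best_feat;       // vector may have reallocated
    nodes[me].thr = best_thr;
    nodes[me].left = left;
    nodes[me].right = right;
    return me;
  }

  int predict(const NumericMatrix &Xt, int row) const {
    int k = 0;
    while (nodes[k].feat >= 0)
      k = (Xt(row, nodes[k].feat) <= nodes[k].thr) ? nodes[k].left
                                                   : nodes[k].right;
    return nodes[k].pred;
  }
};

} // namespace

// [[Rcpp::export(name = ".rf_fit_predict")]]
NumericVector rf_fit_predict(NumericMatrix X, IntegerVector y,
                             NumericMatrix Xtest, int mtry, int ntree,
                             int min_node, int seed) {
  int n = X.nrow(), nt = Xtest.nrow();
  if (y.size() != n) stop("label length mismatch");
  std::mt19937 rng((uint32_t)seed);
  std::vector<double> votes(nt, 0.0);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeBuilder tb(X, y, mtry, min_node, rng);
    tb.nodes.reserve(4 * n);
    tb.build(idx, 0, n);
    for (int r = 0; r < nt; ++r) votes[r] += tb.predict(Xtest, r);
  }
  NumericVector out(nt);
  for (int r = 0; r < nt; ++r) out[r] = votes[r] / ntree;
  return out;
}
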