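// Balanced random forest for binary outcomes, grown for out-of-bag
// evaluation and case proximities. Each tree draws, without replacement, a
// fixed number of cases from each outcome class (class-balanced
// under-sampling), grows an unpruned CART tree with Gini splits on mtry
// randomly chosen features, and votes for its out-of-bag cases. Proximity
// between two cases is the fraction of trees in which they land in the same
// terminal leaf. Uses R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;        // -1: leaf
  double threshold = 0.0;  // go left if x <= threshold
  int left = -1, right = -1;
  int pred = 0;            // leaf majority class
};

// sample k of n indices (0..n-1 positions of src) without replacement
void sample_without_replacement(const std::vector<int>& src, int k,
                                std::vector<int>& out) {
  std::vector<int> pool(src);
  int n = pool.size();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

class TreeGrower {
 public:
  TreeGrower(const NumericMatrix& x, const IntegerVector& y, int mtry)
      : x_(x), y_(y), mtry_(mtry), p_(x.ncol()) {}

  std::vector<Node> nodes;

  void grow(std::vector<int>& idx) {
    nodes.clear();
    build(idx, 0, (int)idx.size());
  }

 private:
  const NumericMatrix& x_;
  const IntegerVector& y_;
  int mtry_, p_;
  std::vector<int>* idx_ = nullptr;

  int build(std::vector<int>& idx, int lo, int hi) {
    int me = (int)nodes.size();
    nodes.push_back(Node());
    int n = hi - lo, n1 = 0;
    for (int i = lo; i < hi; ++i) n1 += y_[idx[i]];
    int n0 = n - n1;
    if (n0 == 0 || n1 == 0 || n < 2) {
      nodes[me].pred = leaf_pred(n0, n1);
      return me;
    }
    // choose best split over mtry random features
    std::vector<int> feats(p_);
    for (int f = 0; f < p_; ++f) feats[f] = f;
    for (int i = 0; i < mtry_; ++i) {
      int j = i + (int)(unif_rand() * (p_ - i));
      if (j >= p_) j = p_ - 1;
      std::swap(feats[i], feats[j]);
    }
    double best_score = -1.0, best_thr = 0.0;
    int best_f = -1;
    std::vector<std::pair<double, int> > buf(n);
    for (int fi = 0; fi < mtry_; ++fi) {
      int f = feats[fi];
      for (int i = 0; i < n; ++i)
        buf[i] = std::make_pair(x_(idx[lo + i], f), y_[idx[lo + i]]);
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;
      int c1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        c1 += buf[i].second;
        if (buf[i].first == buf[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        int c1r = n1 - c1;
        double score =
            (double)((nl - c1) * (double)(nl - c1) + (double)c1 * c1) / nl +
            (double)((nr - c1r) * (double)(nr - c1r) +
                     (double)c1r * c1r) / nr;
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = (buf[i].first + buf[i + 1].first) / 2.0;
        }
      }
    }
    if (best_f < 0) {  // all sampled features constant in this node
      nodes[me].pred = leaf_pred(n0, n1);
      return me;
    }
    // partition idx[lo,hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (x_(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) {  // numeric degeneracy guard
      nodes[me].pred = leaf_pred(n0, n1);
      return me;
    }
    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  int leaf_pred(int n0, int n1) {
    if (n1 > n0) return 1;
    if (n0 > n1) return 0;
    return unif_rand() < 0.5 ? 1 : 0;  // tie broken at random
  }
};

}  // namespace

// [[Rcpp::export(name = ".grow_forest_cpp")]]
List grow_forest_cpp(NumericMatrix x, IntegerVector y, int ntree, int mtry,
                     int per_class_draw, bool proximity) {
  int n = x.nrow();
  std::vector<int> class0, class1;
  for (int i = 0; i < n; ++i) (y[i] ? class1 : class0).push_back(i);
  if (class0.empty() || class1.empty())
    stop("outcome has a single class; cannot grow a balanced forest");
  if (per_class_draw < 1 ||
      per_class_draw > (int)std::min(class0.size(), class1.size()))
    stop("per-class draw must be in [1, n_minority]");

  IntegerVector oob_pos(n), oob_total(n);
  NumericMatrix prox(proximity ? n : 1, proximity ? n : 1);
  std::vector<int> leaf_of(n);
  std::vector<char> inbag(n);

  TreeGrower grower(x, y, mtry);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx;
    idx.reserve(2 * per_class_draw);
    sample_without_replacement(class0, per_class_draw, idx);
    sample_without_replacement(class1, per_class_draw, idx);
    std::fill(inbag.begin(), inbag.end(), 0);
    for (size_t i = 0; i < idx.size(); ++i) inbag[idx[i]] = 1;
    grower.grow(idx);
    const std::vector<Node>& nodes = grower.nodes;
    // route every case to its terminal leaf
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (nodes[node].feature >= 0)
        node = (x(i, nodes[node].feature) <= nodes[node].threshold)
                   ? nodes[node].left
                   : nodes[node].right;
      leaf_of[i] = node;
      if (!inbag[i]) {
        oob_total[i]++;
        oob_pos[i] += nodes[node].pred;
      }
    }
    if (proximity) {
      // accumulate within-leaf pairs
      std::vector<int> order(n);
      for (int i = 0; i < n; ++i) order[i] = i;
      std::sort(order.begin(), order.end(),
                [&](int a, int b) { return leaf_of[a] < leaf_of[b]; });
      int i = 0;
      while (i < n) {
        int j = i;
        while (j < n && leaf_of[order[j]] == leaf_of[order[i]]) ++j;
        for (int a = i; a < j; ++a)
          for (int b = a + 1; b < j; ++b) {
            prox(order[a], order[b]) += 1.0;
            prox(order[b], order[a]) += 1.0;
          }
        i = j;
      }
    }
    if ((t & 63) == 0) Rcpp::checkUserInterrupt();
  }
  if (proximity) {
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) prox(i, j) /= ntree;
      prox(i, i) = 1.0;
    }
  }
  return List::create(Named("oob_pos") = oob_pos,
                      Named("oob_total") = oob_total,
                      Named("proximity") = prox);
}
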