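#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// A compact CART/random-forest implementation for binary classification.
// Trees are grown on bootstrap samples (optionally balanced across classes),
// splits minimise weighted Gini impurity over `mtry` randomly chosen
// features, and the forest probability is the average of terminal-node
// class-1 proportions. All randomness comes from R's RNG (unif_rand), so
// set.seed() upstream makes training fully reproducible.

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;    // go left if x <= thr
  std::vector<int> left, right;
  std::vector<double> pred;   // class-1 proportion at node
};

static int rand_int(int n) {  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static void grow_node(Tree &tr, const NumericMatrix &X, const IntegerVector &y,
                      std::vector<int> &idx, int lo, int hi, int mtry,
                      int min_node, std::vector<int> &featbuf) {
  const int node = (int)tr.feat.size();
  const int n = hi - lo;
  int n1 = 0;
  for (int t = lo; t < hi; ++t) n1 += y[idx[t]];
  const double p1 = (double)n1 / n;

  tr.feat.push_back(-1);
  tr.thr.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.pred.push_back(p1);
  if (n < 2 || n <= min_node || n1 == 0 || n1 == n) return;

  const int p = X.ncol();
  for (int f = 0; f < p; ++f) featbuf[f] = f;
  // partial Fisher-Yates to pick mtry candidate features
  int best_f = -1;
  double best_thr = 0.0, best_gini = 1e18;
  for (int m = 0; m < mtry && m < p; ++m) {
    const int r = m + rand_int(p - m);
    std::swap(featbuf[m], featbuf[r]);
    const int f = featbuf[m];
    // sort sample indices of this node by feature value
    std::vector<std::pair<double, int>> v(n);
    for (int t = 0; t < n; ++t)
      v[t] = std::make_pair(X(idx[lo + t], f), y[idx[lo + t]]);
    std::sort(v.begin(), v.end());
    int left1 = 0;
    for (int t = 0; t < n - 1; ++t) {
      left1 += v[t].second;
      if (v[t + 1].first <= v[t].first) continue;  // not a boundary
      const int nl = t + 1, nr = n - nl;
      const int r1 = n1 - left1;
      const double pl = (double)left1 / nl, pr = (double)r1 / nr;
      const double g = nl * 2.0 * pl * (1 - pl) + nr * 2.0 * pr * (1 - pr);
      if (g < best_gini) {
        best_gini = g;
        best_f = f;
        best_thr = 0.5 * (v[t].first + v[t + 1].first);
      }
    }
  }
  const double parent_gini = n * 2.0 * p1 * (1 - p1);
  if (best_f < 0 || best_gini >= parent_gini - 1e-12) return;

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_f) <= best_thr) std::swap(idx[t], idx[mid++]);
  if (mid == lo || mid == hi) return;

  tr.feat[node] = best_f;
  tr.thr[node] = best_thr;
  tr.left[node] = (int)tr.feat.size();
  grow_node(tr, X, y, idx, lo, mid, mtry, min_node, featbuf);
  tr.right[node] = (int)tr.feat.size();
  grow_node(tr, X, y, idx, mid, hi, mtry, min_node, featbuf);
}

static double tree_predict(const Tree &tr, const NumericMatrix &X, int row) {
  int node = 0;
  while (tr.feat[node] >= 0)
    node = X(row, tr.feat[node]) <= tr.thr[node] ? tr.left[node] : tr.right[node];
  return tr.pred[node];
}

static List tree_to_list(const Tree &tr) {
  return List::create(_["feat"] = wrap(tr.feat), _["thr"] = wrap(tr.thr),
                      _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
                      _["pred"] = wrap(tr.pred));
}

static Tree tree_from_list(const List &l) {
  Tree tr;
  tr.feat = as<std::vector<int>>(l["feat"]);
  tr.thr = as<std::vector<double>>(l["thr"]);
  tr.left = as<std::vector<int>>(l["left"]);
  tr.right = as<std::vector<int>>(l["right"]);
  tr.pred = as<std::vector<double>>(l["pred"]);
  return tr;
}

// [[Rcpp::export(name = ".rf_train")]]
List rf_train(NumericMatrix X, IntegerVector y, int ntree, int mtry,
              int min_node, bool balanced) {
  const int n = X.nrow();
  std::vector<int> cls0, cls1;
  for (int i = 0; i < n; ++i) (y[i] ? cls1 : cls0).push_back(i);
  if (cls0.empty() || cls1.empty())
    stop("training labels contain a single class");

  List trees(ntree);
  NumericVector oob_sum(n);
  IntegerVector oob_n(n);
  std::vector<int> featbuf(X.ncol());
  std::vector<char> inbag(n);
  const int per_class =
      balanced ? (int)std::min(cls0.size(), cls1.size()) : 0;

  for (int b = 0; b < ntree; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx;
    if (balanced) {
      idx.reserve(2 * per_class);
      for (int t = 0; t < per_class; ++t) {
        idx.push_back(cls0[rand_int((int)cls0.size())]);
        idx.push_back(cls1[rand_int((int)cls1.size())]);
      }
    } else {
      idx.reserve(n);
      for (int t = 0; t < n; ++t) idx.push_back(rand_int(n));
    }
    for (size_t t = 0; t < idx.size(); ++t) inbag[idx[t]] = 1;

    Tree tr;
    grow_node(tr, X, y, idx, 0, (int)idx.size(), mtry, min_node, featbuf);
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) {
        oob_sum[i] += tree_predict(tr, X, i);
        oob_n[i] += 1;
      }
    trees[b] = tree_to_list(tr);
  }

  int correct = 0, scored = 0;
  NumericVector oob_prob(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_n[i] > 0) {
      oob_prob[i] = oob_sum[i] / oob_n[i];
      ++scored;
      if ((oob_prob[i] >= 0.5 ? 1 : 0) == y[i]) ++correct;
    }
  const double oob_acc = scored ? (double)correct / scored : NA_REAL;
  return List::create(_["trees"] = trees, _["oob_prob"] = oob_prob,
                      _["oob_accuracy"] = oob_acc);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  std::vector<Tree> forest;
  forest.reserve(B);
  for (int b = 0; b < B; ++b) forest.push_back(tree_from_list(trees[b]));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int b = 0; b < B; ++b) s += tree_predict(forest[b], X, i);
    out[i] = s / B;
  }
  return out;
}
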