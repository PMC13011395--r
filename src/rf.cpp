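// A compact random-forest classifier (binary, Gini impurity, bootstrap
// sampling, mtry random feature subsets). Uses R's RNG so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;  // split feature, -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> pred;  // P(y = 1) in node
};

inline double gini_times_n(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p) * n;
}

int grow(Tree& t, const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& idx, int lo, int hi, int mtry, int min_node,
         std::vector<double>& imp) {
  int n = hi - lo;
  double n1 = 0.0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  int node = (int)t.feat.size();
  t.feat.push_back(-1);
  t.thr.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(n > 0 ? n1 / n : 0.5);
  if (n < min_node || n1 == 0.0 || n1 == (double)n) return node;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {  // partial Fisher-Yates
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  double parent = gini_times_n(n1, n);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<std::pair<double, int> > vals(n);
  for (int j = 0; j < m; ++j) {
    int f = feats[j];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(idx[lo + i], f), y[idx[lo + i]]);
    std::sort(vals.begin(), vals.end());
    double l1 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      double nl = i + 1.0, nr = n - nl, r1 = n1 - l1;
      double gain = parent - gini_times_n(l1, nl) - gini_times_n(r1, nr);
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;  // degenerate split, keep leaf

  imp[best_f] += best_gain;
  t.feat[node] = best_f;
  t.thr[node] = best_thr;
  int l = grow(t, X, y, idx, lo, mid, mtry, min_node, imp);
  t.left[node] = l;
  int r = grow(t, X, y, idx, mid, hi, mtry, min_node, imp);
  t.right[node] = r;
  return node;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_node) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> imp(p, 0.0);
  List forest(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {  // bootstrap sample
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    Tree t;
    grow(t, X, y, idx, 0, n, mtry, min_node, imp);
    forest[b] = List::create(
        _["feat"] = wrap(t.feat), _["thr"] = wrap(t.thr),
        _["left"] = wrap(t.left), _["right"] = wrap(t.right),
        _["pred"] = wrap(t.pred));
  }
  return List::create(_["forest"] = forest, _["importance"] = wrap(imp));
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), B = forest.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List t = forest[b];
    IntegerVector feat = t["feat"];
    NumericVector thr = t["thr"];
    IntegerVector left = t["left"], right = t["right"];
    NumericVector pred = t["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      out[i] += pred[node];
    }
  }
  return out / (double)B;
}
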