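// Decision-tree engine backing the random-forest and gradient-boosting base
// classifiers. Binary classification only; deterministic given the seed
// (private mt19937, no R RNG involvement).
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // leaf value (class-1 fraction or boosting weight)
  int add_node() {
    feature.push_back(-1); threshold.push_back(0.0);
    left.push_back(-1); right.push_back(-1); value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

NumericMatrix pack_tree(const TreeBuf &t) {
  int n = (int)t.feature.size();
  NumericMatrix m(n, 5);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = t.feature[i]; m(i, 1) = t.threshold[i];
    m(i, 2) = t.left[i];    m(i, 3) = t.right[i];
    m(i, 4) = t.value[i];
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left", "right", "value");
  return m;
}

double traverse(const NumericMatrix &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

// Gini split search over one feature for a classification node.
// idx: sample indices at the node (may contain bootstrap duplicates).
bool gini_split_feature(const NumericMatrix &X, const IntegerVector &y,
                        const std::vector<int> &idx, int f, int min_leaf,
                        double parent_imp, SplitResult &best) {
  int n = (int)idx.size();
  std::vector<std::pair<double, int>> v(n);
  for (int i = 0; i < n; ++i) v[i] = {X(idx[i], f), y[idx[i]]};
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return false;
  int total1 = 0;
  for (auto &p : v) total1 += p.second;
  int left1 = 0;
  bool found = false;
  for (int i = 0; i < n - 1; ++i) {
    left1 += v[i].second;
    if (v[i].first == v[i + 1].first) continue;
    int nl = i + 1, nr = n - nl;
    if (nl < min_leaf || nr < min_leaf) continue;
    double pl = (double)left1 / nl, pr = (double)(total1 - left1) / nr;
    double impl = 2.0 * pl * (1.0 - pl), impr = 2.0 * pr * (1.0 - pr);
    double gain = parent_imp - ((double)nl / n) * impl - ((double)nr / n) * impr;
    if (gain > best.gain + 1e-12) {
      best.gain = gain;
      best.feature = f;
      best.threshold = 0.5 * (v[i].first + v[i + 1].first);
      found = true;
    }
  }
  return found;
}

void build_class_tree(const NumericMatrix &X, const IntegerVector &y,
                      std::vector<int> idx, int min_leaf, int max_depth,
                      int mtry, std::mt19937 &gen, TreeBuf &tree,
                      std::vector<double> &importance, int n_total) {
  struct Work { std::vector<int> idx; int node; int depth; };
  int p = X.ncol();
  std::vector<int> feat_pool(p);
  for (int i = 0; i < p; ++i) feat_pool[i] = i;
  std::vector<Work> stack;
  int root = tree.add_node();
  stack.push_back({std::move(idx), root, 0});
  while (!stack.empty()) {
    Work w = std::move(stack.back());
    stack.pop_back();
    int n = (int)w.idx.size();
    int n1 = 0;
    for (int i : w.idx) n1 += y[i];
    double frac1 = (double)n1 / n;
    double imp = 2.0 * frac1 * (1.0 - frac1);
    bool stop = (n1 == 0 || n1 == n) || n < 2 * min_leaf ||
                (max_depth > 0 && w.depth >= max_depth);
    SplitResult best;
    if (!stop) {
      // draw mtry candidate features without replacement (partial Fisher-Yates)
      int m = std::min(mtry, p);
      for (int i = 0; i < m; ++i) {
        int j = i + (int)(gen() % (uint32_t)(p - i));
        std::swap(feat_pool[i], feat_pool[j]);
      }
      for (int i = 0; i < m; ++i) {
        gini_split_feature(X, y, w.idx, feat_pool[i], min_leaf, imp, best);
      }
      if (best.feature < 0) stop = true;
    }
    if (stop) {
      tree.feature[w.node] = -1;
      tree.value[w.node] = frac1;
      continue;
    }
    importance[best.feature] += best.gain * ((double)n / n_total);
    std::vector<int> li, ri;
    for (int i : w.idx) {
      if (X(i, best.feature) <= best.threshold) li.push_back(i);
      else ri.push_back(i);
    }
    tree.feature[w.node] = best.feature;
    tree.threshold[w.node] = best.threshold;
    int ln = tree.add_node(), rn = tree.add_node();
    tree.left[w.node] = ln;
    tree.right[w.node] = rn;
    stack.push_back({std::move(li), ln, w.depth + 1});
    stack.push_back({std::move(ri), rn, w.depth + 1});
  }
}

// Second-order gain split search for a boosting regression tree.
bool grad_split_feature(const NumericMatrix &X, const std::vector<double> &g,
                        const std::vector<double> &h, const std::vector<int> &idx,
                        int f, int min_leaf, double lambda, SplitResult &best) {
  int n = (int)idx.size();
  std::vector<std::pair<double, int>> v(n);
  for (int i = 0; i < n; ++i) v[i] = {X(idx[i], f), idx[i]};
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return false;
  double G = 0, H = 0;
  for (int i = 0; i < n; ++i) { G += g[v[i].second]; H += h[v[i].second]; }
  double parent_score = G * G / (H + lambda);
  double GL = 0, HL = 0;
  bool found = false;
  for (int i = 0; i < n - 1; ++i) {
    GL += g[v[i].second]; HL += h[v[i].second];
    if (v[i].first == v[i + 1].first) continue;
    int nl = i + 1, nr = n - nl;
    if (nl < min_leaf || nr < min_leaf) continue;
    double GR = G - GL, HR = H - HL;
    double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent_score);
    if (gain > best.gain + 1e-12) {
      best.gain = gain;
      best.feature = f;
      best.threshold = 0.5 * (v[i].first + v[i + 1].first);
      found = true;
    }
  }
  return found;
}

void build_grad_tree(const NumericMatrix &X, const std::vector<double> &g,
                     const std::vector<double> &h, int min_leaf, int max_depth,
                     double lambda, TreeBuf &tree) {
  struct Work { std::vector<int> idx; int node; int depth; };
  int p = X.ncol();
  std::vector<Work> stack;
  int root = tree.add_node();
  std::vector<int> all(X.nrow());
  for (int i = 0; i < (int)all.size(); ++i) all[i] = i;
  stack.push_back({std::move(all), root, 0});
  while (!stack.empty()) {
    Work w = std::move(stack.back());
    stack.pop_back();
    int n = (int)w.idx.size();
    double G = 0, H = 0;
    for (int i : w.idx) { G += g[i]; H += h[i]; }
    bool stop = n < 2 * min_leaf || (max_depth > 0 && w.depth >= max_depth);
    SplitResult best;
    if (!stop) {
      for (int f = 0; f < p; ++f) grad_split_feature(X, g, h, w.idx, f, min_leaf, lambda, best);
      if (best.feature < 0) stop = true;
    }
    if (stop) {
      tree.feature[w.node] = -1;
      tree.value[w.node] = -G / (H + lambda);
      continue;
    }
    std::vector<int> li, ri;
    for (int i : w.idx) {
      if (X(i, best.feature) <= best.threshold) li.push_back(i);
      else ri.push_back(i);
    }
    tree.feature[w.node] = best.feature;
    tree.threshold[w.node] = best.threshold;
    int ln = tree.add_node(), rn = tree.add_node();
    tree.left[w.node] = ln;
    tree.right[w.node] = rn;
    stack.push_back({std::move(li), ln, w.depth + 1});
    stack.push_back({std::move(ri), rn, w.depth + 1});
  }
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_leaf, int max_depth, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 gen((uint32_t)seed);
  List trees(ntree);
  std::vector<double> importance(p, 0.0);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = (int)(gen() % (uint32_t)n);
    TreeBuf tb;
    build_class_tree(X, y, std::move(idx), min_leaf, max_depth, mtry, gen,
                     tb, importance, n);
    trees[t] = pack_tree(tb);
  }
  NumericVector imp(p);
  double tot = 0;
  for (int f = 0; f < p; ++f) tot += importance[f];
  for (int f = 0; f < p; ++f) imp[f] = tot > 0 ? importance[f] / tot : 0.0;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += traverse(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// [[Rcpp::export]]
List xgb_fit_cpp(NumericMatrix X, IntegerVector y, int nrounds, int max_depth,
                 double eta, double lambda, int min_leaf) {
  int n = X.nrow();
  double ybar = 0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double base = std::log(ybar / (1.0 - ybar));
  std::vector<double> f(n, base), g(n), h(n);
  List trees(nrounds);
  for (int r = 0; r < nrounds; ++r) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-f[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-12);
    }
    TreeBuf tb;
    build_grad_tree(X, g, h, min_leaf, max_depth, lambda, tb);
    NumericMatrix tree = pack_tree(tb);
    trees[r] = tree;
    for (int i = 0; i < n; ++i) f[i] += eta * traverse(tree, X, i);
  }
  return List::create(_["trees"] = trees, _["base"] = base, _["eta"] = eta);
}

// [[Rcpp::export]]
NumericVector xgb_predict_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  double base = model["base"], eta = model["eta"];
  int n = X.nrow();
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += eta * traverse(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
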