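// Multiclass gradient-boosted regression trees (softmax objective).
// Exact greedy splits with second-order gain, as in the reference GBT
// literature: gain = 0.5 * (GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l)) - gamma,
// leaf weight = -G/(H+l). Row and feature subsampling per tree. Uses R's RNG
// so results are reproducible under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature = -1;       // -1 for leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

struct SplitInfo {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
  std::vector<int> left_rows, right_rows;
};

static SplitInfo best_split(const NumericMatrix& X,
                            const std::vector<double>& g,
                            const std::vector<double>& h,
                            const std::vector<int>& rows,
                            const std::vector<int>& feats,
                            double lambda, double gamma,
                            double min_child_weight) {
  SplitInfo best;
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  const double parent = G * G / (H + lambda);
  std::vector<std::pair<double, int> > vals(rows.size());
  for (int f : feats) {
    for (size_t i = 0; i < rows.size(); ++i)
      vals[i] = std::make_pair(X(rows[i], f), rows[i]);
    std::sort(vals.begin(), vals.end());
    double GL = 0.0, HL = 0.0;
    for (size_t i = 0; i + 1 < vals.size(); ++i) {
      GL += g[vals[i].second];
      HL += h[vals[i].second];
      if (vals[i].first == vals[i + 1].first) continue;
      double GR = G - GL, HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda)
                           - parent) - gamma;
      if (gain > best.gain) {
        best.gain = gain;
        best.feature = f;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best.feature >= 0) {
    for (int r : rows) {
      if (X(r, best.feature) < best.threshold) best.left_rows.push_back(r);
      else best.right_rows.push_back(r);
    }
  }
  return best;
}

static double tree_predict(const std::vector<Node>& tree, int node,
                           const NumericMatrix& X, int row) {
  while (tree[node].feature >= 0) {
    node = (X(row, tree[node].feature) < tree[node].threshold)
      ? tree[node].left : tree[node].right;
  }
  return tree[node].value;
}

static List tree_to_list(const std::vector<Node>& tree) {
  int n = (int)tree.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), value(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = tree[i].feature;
    threshold[i] = tree[i].threshold;
    left[i] = tree[i].left;
    right[i] = tree[i].right;
    value[i] = tree[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

static std::vector<Node> tree_from_list(const List& lst) {
  IntegerVector feature = lst["feature"], left = lst["left"],
    right = lst["right"];
  NumericVector threshold = lst["threshold"], value = lst["value"];
  std::vector<Node> tree(feature.size());
  for (int i = 0; i < feature.size(); ++i) {
    tree[i].feature = feature[i];
    tree[i].threshold = threshold[i];
    tree[i].left = left[i];
    tree[i].right = right[i];
    tree[i].value = value[i];
  }
  return tree;
}

// [[Rcpp::export]]
List gbt_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                 int n_rounds, double learning_rate, int max_depth,
                 double min_child_weight, double lambda, double gamma,
                 double subsample, int colsample_count) {
  const int n = X.nrow(), p = X.ncol(), K = n_classes;
  std::vector<double> margin((size_t)n * K, 0.0);
  List trees(n_rounds * K);
  std::vector<double> g(n), h(n);
  std::vector<double> prob((size_t)n * K);
  RNGScope scope;
  for (int round = 0; round < n_rounds; ++round) {
    // softmax probabilities from current margins
    for (int i = 0; i < n; ++i) {
      double mx = margin[(size_t)i * K];
      for (int k = 1; k < K; ++k)
        mx = std::max(mx, margin[(size_t)i * K + k]);
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        prob[(size_t)i * K + k] = std::exp(margin[(size_t)i * K + k] - mx);
        s += prob[(size_t)i * K + k];
      }
      for (int k = 0; k < K; ++k) prob[(size_t)i * K + k] /= s;
    }
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) {
        double pk = prob[(size_t)i * K + k];
        g[i] = pk - (y[i] == k ? 1.0 : 0.0);
        h[i] = std::max(pk * (1.0 - pk), 1e-16);
      }
      // row subsample (without replacement)
      std::vector<int> rows;
      rows.reserve(n);
      if (subsample >= 1.0) {
        for (int i = 0; i < n; ++i) rows.push_back(i);
      } else {
        int target = std::max(1, (int)std::floor(subsample * n + 0.5));
        std::vector<int> perm(n);
        for (int i = 0; i < n; ++i) perm[i] = i;
        for (int i = 0; i < target; ++i) {
          int j = i + (int)std::floor(unif_rand() * (n - i));
          if (j >= n) j = n - 1;
          std::swap(perm[i], perm[j]);
        }
        rows.assign(perm.begin(), perm.begin() + target);
      }
      // feature subsample: restrict X columns via a masked copy of indices
      std::vector<int> feats;
      if (colsample_count >= p || colsample_count <= 0) {
        for (int f = 0; f < p; ++f) feats.push_back(f);
      } else {
        std::vector<int> perm(p);
        for (int f = 0; f < p; ++f) perm[f] = f;
        for (int f = 0; f < colsample_count; ++f) {
          int j = f + (int)std::floor(unif_rand() * (p - f));
          if (j >= p) j = p - 1;
          std::swap(perm[f], perm[j]);
        }
        feats.assign(perm.begin(), perm.begin() + colsample_count);
      }
      // grow tree on the selected rows/features
      std::vector<Node> tree;
      // wrap best_split feature restriction by temporarily growing with
      // a feature-filtered recursion
      struct Grower {
        const NumericMatrix& X;
        const std::vector<double>& g;
        const std::vector<double>& h;
        const std::vector<int>& feats;
        double lambda, gamma, min_child_weight, eta;
        int max_depth;
        std::vector<Node>& tree;
        int grow_node(const std::vector<int>& rows, int depth) {
          int idx = (int)tree.size();
          tree.push_back(Node());
          double G = 0.0, H = 0.0;
          for (int r : rows) { G += g[r]; H += h[r]; }
          bool leaf = depth >= max_depth || rows.size() < 2;
          SplitInfo sp;
          if (!leaf) {
            sp = best_split(X, g, h, rows, feats, lambda, gamma,
                            min_child_weight);
            if (sp.feature < 0) leaf = true;
          }
          if (leaf) {
            tree[idx].value = -eta * G / (H + lambda);
            return idx;
          }
          tree[idx].feature = sp.feature;
          tree[idx].threshold = sp.threshold;
          int l = grow_node(sp.left_rows, depth + 1);
          int r = grow_node(sp.right_rows, depth + 1);
          tree[idx].left = l;
          tree[idx].right = r;
          return idx;
        }
      } grower{X, g, h, feats, lambda, gamma, min_child_weight,
               learning_rate, max_depth, tree};
      grower.grow_node(rows, 0);
      // update margins for class k with the new tree (all rows)
      for (int i = 0; i < n; ++i)
        margin[(size_t)i * K + k] += tree_predict(tree, 0, X, i);
      trees[round * K + k] = tree_to_list(tree);
    }
  }
  return List::create(_["trees"] = trees, _["n_classes"] = K,
                      _["n_rounds"] = n_rounds);
}

// [[Rcpp::export]]
NumericMatrix gbt_predict_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  int K = as<int>(model["n_classes"]);
  int n_rounds = as<int>(model["n_rounds"]);
  const int n = X.nrow();
  NumericMatrix margin(n, K);
  for (int round = 0; round < n_rounds; ++round) {
    for (int k = 0; k < K; ++k) {
      std::vector<Node> tree = tree_from_list(trees[round * K + k]);
      for (int i = 0; i < n; ++i)
        margin(i, k) += tree_predict(tree, 0, X, i);
    }
  }
  NumericMatrix prob(n, K);
  for (int i = 0; i < n; ++i) {
    double mx = margin(i, 0);
    for (int k = 1; k < K; ++k) mx = std::max(mx, margin(i, k));
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      prob(i, k) = std::exp(margin(i, k) - mx);
      s += prob(i, k);
    }
    for (int k = 0; k < K; ++k) prob(i, k) /= s;
  }
  return prob;
}
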