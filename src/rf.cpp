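// Random-forest classifier (CART trees, Gini impurity, bootstrap,
// mtry random features per split) reduced to what the pipeline needs:
// mean-decrease-in-impurity feature importances. Compiled because the
// importance scan runs over ~1000 wavenumber features x hundreds of
// spectra x hundreds of trees.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Forest {
  const NumericMatrix &X;
  int n_classes;
  int mtry;
  int min_node;
  std::vector<double> importance;
  double n_total;

  Forest(const NumericMatrix &X_, int n_classes_, int mtry_, int min_node_)
      : X(X_), n_classes(n_classes_), mtry(mtry_), min_node(min_node_),
        importance(X_.ncol(), 0.0), n_total(0.0) {}

  static double gini(const std::vector<double> &counts, double n) {
    double g = 1.0;
    for (double c : counts) {
      double p = c / n;
      g -= p * p;
    }
    return g;
  }

  void grow(std::vector<int> &idx, const IntegerVector &y,
            std::mt19937 &rng, std::vector<int> &feat_pool) {
    const double n = static_cast<double>(idx.size());
    std::vector<double> counts(n_classes, 0.0);
    for (int i : idx) counts[y[i]] += 1.0;
    int present = 0;
    for (double c : counts)
      if (c > 0) ++present;
    if (present <= 1 || static_cast<int>(idx.size()) < 2 * min_node ||
        idx.size() < 2)
      return;  // leaf: pure or too small

    const double node_gini = gini(counts, n);
    double best_gain = 0.0;
    int best_feat = -1;
    double best_thr = 0.0;

    // sample mtry features without replacement (partial Fisher-Yates)
    const int p = X.ncol();
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(feat_pool[j], feat_pool[pick(rng)]);
    }

    std::vector<std::pair<double, int> > vals;
    vals.reserve(idx.size());
    std::vector<double> left(n_classes);
    for (int j = 0; j < mtry; ++j) {
      const int f = feat_pool[j];
      vals.clear();
      for (int i : idx) vals.push_back(std::make_pair(X(i, f), y[i]));
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(left.begin(), left.end(), 0.0);
      double nl = 0.0;
      for (size_t s = 0; s + 1 < vals.size(); ++s) {
        left[vals[s].second] += 1.0;
        nl += 1.0;
        if (vals[s].first == vals[s + 1].first) continue;
        const double nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double gl = 1.0, gr = 1.0;
        for (int c = 0; c < n_classes; ++c) {
          double pl = left[c] / nl;
          double pr = (counts[c] - left[c]) / nr;
          gl -= pl * pl;
          gr -= pr * pr;
        }
        const double gain = node_gini - (nl / n) * gl - (nr / n) * gr;
        if (gain > best_gain + 1e-15) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[s].first + vals[s + 1].first);
        }
      }
    }
    if (best_feat < 0) return;  // no usable split among sampled features

    importance[best_feat] += (n / n_total) * best_gain;

    std::vector<int> li, ri;
    li.reserve(idx.size());
    ri.reserve(idx.size());
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr)
        li.push_back(i);
      else
        ri.push_back(i);
    }
    idx.clear();
    idx.shrink_to_fit();
    grow(li, y, rng, feat_pool);
    grow(ri, y, rng, feat_pool);
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_importance_cpp")]]
NumericVector rf_importance_cpp(NumericMatrix X, IntegerVector y,
                                int n_classes, int n_trees, int mtry,
                                int min_node, int seed) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  Forest forest(X, n_classes, mtry, min_node);
  forest.n_total = static_cast<double>(n);
  std::vector<int> feat_pool(p);
  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng(static_cast<uint32_t>(seed) + 0x9e3779b9u * (t + 1));
    std::uniform_int_distribution<int> draw(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = draw(rng);
    for (int f = 0; f < p; ++f) feat_pool[f] = f;
    forest.grow(idx, y, rng, feat_pool);
  }
  NumericVector out(p);
  for (int f = 0; f < p; ++f) out[f] = forest.importance[f] / n_trees;
  return out;
}
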