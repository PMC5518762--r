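// Weighted CART regression trees plus the two tree ensembles built on them:
// a bagged random forest (per-split feature subsampling) and Newton-step
// logistic gradient boosting.  All randomness comes from R's RNG so fits
// are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x < threshold
  std::vector<double> value;     // node prediction (weighted mean)
  std::vector<int> left, right;
  std::vector<std::vector<int> > leaf_rows; // training rows per leaf (for BRT)
};

static int grow_node(Tree &tr, const NumericMatrix &X, const NumericVector &y,
                     const NumericVector &w, std::vector<int> &idx,
                     int depth, int max_depth, int min_obs, int mtry,
                     bool keep_rows) {
  const int m = (int)idx.size();
  double W = 0.0, S = 0.0;
  for (int k = 0; k < m; ++k) { W += w[idx[k]]; S += w[idx[k]] * y[idx[k]]; }
  const double node_val = (W > 0.0) ? S / W : 0.0;

  int node = (int)tr.feature.size();
  tr.feature.push_back(-1);
  tr.threshold.push_back(0.0);
  tr.value.push_back(node_val);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.leaf_rows.push_back(std::vector<int>());

  bool pure = true;
  for (int k = 1; k < m; ++k)
    if (y[idx[k]] != y[idx[0]]) { pure = false; break; }

  if (depth >= max_depth || m < 2 * min_obs || pure) {
    if (keep_rows) tr.leaf_rows[node] = idx;
    return node;
  }

  // sample mtry candidate features without replacement (partial Fisher-Yates)
  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int ncand = std::min(mtry, p);
  for (int j = 0; j < ncand; ++j) {
    int r = j + (int)std::floor(unif_rand() * (p - j));
    if (r >= p) r = p - 1;
    std::swap(feats[j], feats[r]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  const double base = (W > 0.0) ? S * S / W : 0.0;
  std::vector<int> ord(idx);

  for (int jj = 0; jj < ncand; ++jj) {
    const int j = feats[jj];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, j) < X(b, j);
    });
    double Wl = 0.0, Sl = 0.0;
    for (int k = 0; k < m - 1; ++k) {
      const int i = ord[k];
      Wl += w[i]; Sl += w[i] * y[i];
      if (X(ord[k], j) >= X(ord[k + 1], j)) continue; // no boundary here
      if (k + 1 < min_obs || m - k - 1 < min_obs) continue;
      const double Wr = W - Wl, Sr = S - Sl;
      if (Wl <= 0.0 || Wr <= 0.0) continue;
      const double gain = Sl * Sl / Wl + Sr * Sr / Wr - base;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (X(ord[k], j) + X(ord[k + 1], j));
      }
    }
  }

  if (best_feat < 0) {
    if (keep_rows) tr.leaf_rows[node] = idx;
    return node;
  }

  std::vector<int> lidx, ridx;
  lidx.reserve(m); ridx.reserve(m);
  for (int k = 0; k < m; ++k) {
    if (X(idx[k], best_feat) < best_thr) lidx.push_back(idx[k]);
    else ridx.push_back(idx[k]);
  }
  if (lidx.empty() || ridx.empty()) { // numeric tie safety
    if (keep_rows) tr.leaf_rows[node] = idx;
    return node;
  }

  tr.feature[node] = best_feat;
  tr.threshold[node] = best_thr;
  int l = grow_node(tr, X, y, w, lidx, depth + 1, max_depth, min_obs, mtry,
                    keep_rows);
  int r = grow_node(tr, X, y, w, ridx, depth + 1, max_depth, min_obs, mtry,
                    keep_rows);
  tr.left[node] = l;
  tr.right[node] = r;
  return node;
}

static List tree_to_list(const Tree &tr) {
  return List::create(_["feature"] = wrap(tr.feature),
                      _["threshold"] = wrap(tr.threshold),
                      _["value"] = wrap(tr.value),
                      _["left"] = wrap(tr.left),
                      _["right"] = wrap(tr.right));
}

static double predict_one(const IntegerVector &feature,
                          const NumericVector &threshold,
                          const NumericVector &value,
                          const IntegerVector &left,
                          const IntegerVector &right,
                          const NumericMatrix &X, int i) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(i, feature[node]) < threshold[node]) ? left[node] : right[node];
  return value[node];
}

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, NumericVector y, NumericVector w,
               int mtry, int max_depth, int min_obs) {
  Tree tr;
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  grow_node(tr, X, y, w, idx, 0, max_depth, min_obs, mtry, false);
  return tree_to_list(tr);
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
    right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = predict_one(feature, threshold, value, left, right, X, i);
  return out;
}

// weighted sample of n indices with replacement, probs proportional to w
static std::vector<int> weighted_boot(const NumericVector &w, int n) {
  std::vector<double> cum(w.size());
  double tot = 0.0;
  for (int i = 0; i < w.size(); ++i) { tot += w[i]; cum[i] = tot; }
  std::vector<int> out(n);
  for (int k = 0; k < n; ++k) {
    double u = unif_rand() * tot;
    out[k] = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (out[k] >= (int)cum.size()) out[k] = (int)cum.size() - 1;
  }
  return out;
}

// [[Rcpp::export(name = ".rf_grow")]]
List rf_grow(NumericMatrix X, NumericVector y, NumericVector w,
             int ntree, int mtry, int max_depth, int min_obs) {
  const int n = X.nrow();
  List forest(ntree);
  NumericVector unit(n, 1.0);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx = weighted_boot(w, n);
    Tree tr;
    // bootstrap already encodes the case weights; grow unweighted
    grow_node(tr, X, y, unit, idx, 0, max_depth, min_obs, mtry, false);
    forest[t] = tree_to_list(tr);
  }
  return forest;
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List forest, NumericMatrix X) {
  const int n = X.nrow(), ntree = forest.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    List tree = forest[t];
    IntegerVector feature = tree["feature"], left = tree["left"],
      right = tree["right"];
    NumericVector threshold = tree["threshold"], value = tree["value"];
    for (int i = 0; i < n; ++i)
      out[i] += predict_one(feature, threshold, value, left, right, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// [[Rcpp::export(name = ".brt_grow")]]
List brt_grow(NumericMatrix X, NumericVector y, NumericVector w,
              int ntree, double shrinkage, int max_depth, int min_obs,
              double bag_frac) {
  const int n = X.nrow();
  double sw = 0.0, sy = 0.0;
  for (int i = 0; i < n; ++i) { sw += w[i]; sy += w[i] * y[i]; }
  double p0 = sy / sw;
  p0 = std::min(std::max(p0, 1e-6), 1.0 - 1e-6);
  const double f0 = std::log(p0 / (1.0 - p0));

  std::vector<double> f(n, f0), prob(n);
  NumericVector resid(n);
  List trees(ntree);

  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  const int nbag = std::max(2 * min_obs, (int)std::floor(bag_frac * n));

  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) {
      prob[i] = 1.0 / (1.0 + std::exp(-f[i]));
      resid[i] = y[i] - prob[i];
    }
    // bag: uniform subsample without replacement
    std::vector<int> bag(rows);
    int m = std::min(nbag, n);
    for (int k = 0; k < m; ++k) {
      int r = k + (int)std::floor(unif_rand() * (n - k));
      if (r >= n) r = n - 1;
      std::swap(bag[k], bag[r]);
    }
    bag.resize(m);

    Tree tr;
    grow_node(tr, X, resid, w, bag, 0, max_depth, min_obs, 1000000, true);

    // Newton leaf values for Bernoulli loss: sum(w r) / sum(w p (1-p))
    for (size_t nd = 0; nd < tr.feature.size(); ++nd) {
      if (tr.feature[nd] >= 0) continue;
      double num = 0.0, den = 0.0;
      for (int i : tr.leaf_rows[nd]) {
        num += w[i] * resid[i];
        den += w[i] * prob[i] * (1.0 - prob[i]);
      }
      double v = (den > 1e-12) ? num / den : 0.0;
      if (v > 4.0) v = 4.0;
      if (v < -4.0) v = -4.0;
      tr.value[nd] = v;
    }
    // update f on all rows (walk the tree struct directly)
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr.feature[node] >= 0)
        node = (X(i, tr.feature[node]) < tr.threshold[node])
          ? tr.left[node] : tr.right[node];
      f[i] += shrinkage * tr.value[node];
    }
    trees[t] = tree_to_list(tr);
  }
  return List::create(_["f0"] = f0, _["shrinkage"] = shrinkage,
                      _["trees"] = trees);
}

// [[Rcpp::export(name = ".brt_predict")]]
NumericVector brt_predict(List model, NumericMatrix X) {
  const double f0 = as<double>(model["f0"]);
  const double shrink = as<double>(model["shrinkage"]);
  List trees = model["trees"];
  const int n = X.nrow();
  NumericVector f(n, f0);
  for (int t = 0; t < trees.size(); ++t) {
    List tree = trees[t];
    IntegerVector feature = tree["feature"], left = tree["left"],
      right = tree["right"];
    NumericVector threshold = tree["threshold"], value = tree["value"];
    for (int i = 0; i < n; ++i)
      f[i] += shrink * predict_one(feature, threshold, value, left, right, X, i);
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-f[i]));
  return out;
}
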