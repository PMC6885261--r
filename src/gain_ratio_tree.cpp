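// Weighted gain-ratio decision tree on continuous features.
//
// C4.5-style selection: for every candidate feature the best midpoint
// threshold by weighted information gain is found; among candidate features
// whose gain is at least the mean candidate gain, the split with the highest
// gain ratio wins. Trees are unpruned. Random-tree mode draws a fresh uniform
// feature subset at every node (R's RNG, so set.seed() gives determinism).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // x <= threshold goes left
  std::vector<int> left, right;
  std::vector<int> pred;         // 0-based class index
  std::vector<double> dist;      // nodes x K class-weight proportions
};

const double EPS_GAIN = 1e-12;

double entropy(const std::vector<double>& cnt, double total) {
  if (total <= 0) return 0.0;
  double h = 0.0;
  for (double c : cnt) {
    if (c > 0) {
      double p = c / total;
      h -= p * std::log2(p);
    }
  }
  return h;
}

// Best midpoint threshold for one feature over the rows of this node.
// Returns gain; fills threshold and split_info. gain < 0 => no valid split.
double best_split_for_feature(const NumericMatrix& X, const IntegerVector& y,
                              const NumericVector& w,
                              const std::vector<int>& rows, int K, int f,
                              double parent_entropy, double w_total,
                              double& thr_out, double& si_out) {
  const int m = (int)rows.size();
  std::vector<int> ord(rows);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return X(a, f) < X(b, f);
  });
  std::vector<double> left_cnt(K, 0.0), right_cnt(K, 0.0);
  for (int r : ord) right_cnt[y[r]] += w[r];
  double w_left = 0.0, w_right = w_total;
  double best_gain = -1.0;
  for (int i = 0; i + 1 < m; ++i) {
    int r = ord[i];
    left_cnt[y[r]] += w[r];
    right_cnt[y[r]] -= w[r];
    w_left += w[r];
    w_right -= w[r];
    double xa = X(r, f), xb = X(ord[i + 1], f);
    if (xb <= xa) continue;  // not a boundary between distinct values
    double gain = parent_entropy -
      (w_left / w_total) * entropy(left_cnt, w_left) -
      (w_right / w_total) * entropy(right_cnt, w_right);
    if (gain > best_gain) {
      best_gain = gain;
      thr_out = xa + (xb - xa) / 2.0;
      double pl = w_left / w_total, pr = w_right / w_total;
      si_out = -pl * std::log2(pl) - pr * std::log2(pr);
    }
  }
  return best_gain;
}

// Draw `mtry` distinct feature indices via partial Fisher-Yates on R's RNG.
std::vector<int> sample_features(int d, int mtry) {
  std::vector<int> idx(d);
  for (int i = 0; i < d; ++i) idx[i] = i;
  for (int i = 0; i < mtry; ++i) {
    int j = i + (int)std::floor(unif_rand() * (d - i));
    if (j >= d) j = d - 1;
    std::swap(idx[i], idx[j]);
  }
  idx.resize(mtry);
  return idx;
}

int grow(const NumericMatrix& X, const IntegerVector& y,
         const NumericVector& w, std::vector<int>& rows, int K, int mtry,
         int depth, int max_depth, double min_leaf_w, int min_split,
         TreeBuf& tb) {
  const int node = (int)tb.feature.size();
  tb.feature.push_back(-1);
  tb.threshold.push_back(0.0);
  tb.left.push_back(-1);
  tb.right.push_back(-1);
  tb.pred.push_back(0);
  // class distribution + majority (tie -> smallest class index)
  std::vector<double> cnt(K, 0.0);
  double w_total = 0.0;
  for (int r : rows) {
    cnt[y[r]] += w[r];
    w_total += w[r];
  }
  int best_c = 0;
  for (int c = 1; c < K; ++c) {
    if (cnt[c] > cnt[best_c]) best_c = c;
  }
  tb.pred[node] = best_c;
  for (int c = 0; c < K; ++c) {
    tb.dist.push_back(w_total > 0 ? cnt[c] / w_total : (c == 0 ? 1.0 : 0.0));
  }
  double parent_entropy = entropy(cnt, w_total);
  bool pure = parent_entropy <= 0.0;
  if (pure || (int)rows.size() < min_split || depth >= max_depth) return node;

  const int d = X.ncol();
  std::vector<int> feats;
  if (mtry > 0 && mtry < d) {
    feats = sample_features(d, mtry);
  } else {
    feats.resize(d);
    for (int i = 0; i < d; ++i) feats[i] = i;
  }
  std::sort(feats.begin(), feats.end());  // deterministic tie-break order

  std::vector<double> gains(feats.size(), -1.0), thrs(feats.size(), 0.0),
      sis(feats.size(), 0.0);
  double gain_sum = 0.0;
  int n_valid = 0;
  for (size_t i = 0; i < feats.size(); ++i) {
    gains[i] = best_split_for_feature(X, y, w, rows, K, feats[i],
                                      parent_entropy, w_total, thrs[i],
                                      sis[i]);
    if (gains[i] >= 0) {
      gain_sum += gains[i];
      ++n_valid;
    }
  }
  if (n_valid == 0) return node;
  double mean_gain = gain_sum / n_valid;
  int pick = -1;
  double best_gr = -1.0;
  for (size_t i = 0; i < feats.size(); ++i) {
    if (gains[i] < 0 || gains[i] < mean_gain - 1e-12) continue;
    double gr = sis[i] > 0 ? gains[i] / sis[i] : 0.0;
    if (gr > best_gr + 1e-15) {
      best_gr = gr;
      pick = (int)i;
    }
  }
  if (pick < 0 || gains[pick] <= EPS_GAIN) return node;

  int f = feats[pick];
  double thr = thrs[pick];
  std::vector<int> lrows, rrows;
  double lw = 0.0, rw = 0.0;
  for (int r : rows) {
    if (X(r, f) <= thr) {
      lrows.push_back(r);
      lw += w[r];
    } else {
      rrows.push_back(r);
      rw += w[r];
    }
  }
  if (lrows.empty() || rrows.empty() || lw < min_leaf_w || rw < min_leaf_w) {
    return node;
  }
  rows.clear();
  rows.shrink_to_fit();
  tb.feature[node] = f;
  tb.threshold[node] = thr;
  int l = grow(X, y, w, lrows, K, mtry, depth + 1, max_depth, min_leaf_w,
               min_split, tb);
  tb.left[node] = l;
  int r = grow(X, y, w, rrows, K, mtry, depth + 1, max_depth, min_leaf_w,
               min_split, tb);
  tb.right[node] = r;
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".fit_tree_cpp")]]
List fit_tree_cpp(NumericMatrix X, IntegerVector y, NumericVector w, int K,
                  int mtry, int max_depth, double min_leaf_w, int min_split) {
  const int n = X.nrow();
  if (n < 1) stop("empty dataset");
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  TreeBuf tb;
  grow(X, y, w, rows, K, mtry, 0,
       max_depth > 0 ? max_depth : 1000000, min_leaf_w, min_split, tb);
  const int nn = (int)tb.feature.size();
  NumericMatrix dist(nn, K);
  for (int i = 0; i < nn; ++i) {
    for (int c = 0; c < K; ++c) dist(i, c) = tb.dist[(size_t)i * K + c];
  }
  return List::create(_["feature"] = wrap(tb.feature),
                      _["threshold"] = wrap(tb.threshold),
                      _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
                      _["pred"] = wrap(tb.pred), _["dist"] = dist);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
List predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  IntegerVector pred = tree["pred"];
  NumericMatrix dist = tree["dist"];
  const int n = X.nrow(), K = dist.ncol();
  IntegerVector out(n);
  NumericMatrix scores(n, K);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = pred[node];
    for (int c = 0; c < K; ++c) scores(i, c) = dist(node, c);
  }
  return List::create(_["pred"] = out, _["scores"] = scores);
}
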