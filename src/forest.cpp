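// Bagged regression trees with mtry feature subsampling and OOB permutation
// importance. Trees are stored as flat arrays so fitted forests can be
// serialized as plain R lists.
//
// Conventions: bootstrap with replacement (n draws), candidate features per
// split = mtry, minimum leaf size min_leaf, no depth cap, splits chosen by
// exhaustive variance-reduction scan over the mtry candidates. All randomness
// is drawn from R's RNG so set.seed() makes training reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Tree {
  // node arrays; children index -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;
};

int grow_node(Tree &tr, const arma::mat &X, const arma::vec &y,
              std::vector<int> &rows, int lo, int hi, int mtry, int min_leaf) {
  const int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int i = lo; i < hi; ++i) {
    const double v = y[rows[i]];
    sum += v; sum2 += v * v;
  }
  const double mean = sum / n;
  const int node = (int)tr.feature.size();
  tr.feature.push_back(-1); tr.threshold.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1);
  tr.value.push_back(mean);

  const double sse = sum2 - sum * mean;
  if (n < 2 * min_leaf || sse <= 1e-12) return node;

  const int p = (int)X.n_cols;
  // sample mtry distinct candidate features via partial Fisher-Yates
  std::vector<int> feat(p);
  for (int j = 0; j < p; ++j) feat[j] = j;
  const int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feat[j], feat[k]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  std::vector<std::pair<double, double>> xy(n);
  for (int jj = 0; jj < m; ++jj) {
    const int f = feat[jj];
    for (int i = 0; i < n; ++i) {
      const int r = rows[lo + i];
      xy[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;
    double lsum = 0.0, lsum2 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      const double v = xy[i].second;
      lsum += v; lsum2 += v * v;
      const int nl = i + 1, nr = n - nl;
      if (xy[i].first == xy[i + 1].first) continue;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double rsum = sum - lsum, rsum2 = sum2 - lsum2;
      const double sse_l = lsum2 - lsum * lsum / nl;
      const double sse_r = rsum2 - rsum * rsum / nr;
      const double gain = sse - sse_l - sse_r;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
      }
    }
  }
  if (best_feat < 0) return node;

  // partition rows[lo..hi) in place
  int i = lo, j = hi - 1;
  while (i <= j) {
    if (X(rows[i], best_feat) <= best_thr) { ++i; }
    else { std::swap(rows[i], rows[j]); --j; }
  }
  const int mid = i;
  if (mid == lo || mid == hi) return node;  // numeric ties; give up

  tr.feature[node] = best_feat;
  tr.threshold[node] = best_thr;
  tr.left[node] = grow_node(tr, X, y, rows, lo, mid, mtry, min_leaf);
  tr.right[node] = grow_node(tr, X, y, rows, mid, hi, mtry, min_leaf);
  return node;
}

double predict_tree(const Tree &tr, const arma::mat &X, int row) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    node = (X(row, tr.feature[node]) <= tr.threshold[node]) ? tr.left[node]
                                                            : tr.right[node];
  }
  return tr.value[node];
}

double predict_tree_vec(const Tree &tr, const arma::rowvec &x) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    node = (x[tr.feature[node]] <= tr.threshold[node]) ? tr.left[node]
                                                       : tr.right[node];
  }
  return tr.value[node];
}

Tree tree_from_list(const List &tl) {
  Tree tr;
  tr.feature = as<std::vector<int>>(tl["feature"]);
  tr.threshold = as<std::vector<double>>(tl["threshold"]);
  tr.left = as<std::vector<int>>(tl["left"]);
  tr.right = as<std::vector<int>>(tl["right"]);
  tr.value = as<std::vector<double>>(tl["value"]);
  return tr;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_forest_fit")]]
List cpp_forest_fit(const arma::mat &X, const arma::vec &y, int n_trees,
                    int mtry, int min_leaf, bool importance) {
  RNGScope scope;
  const int n = (int)X.n_rows;
  List trees(n_trees);
  // OOB accumulation for predictions and permutation importance
  arma::vec oob_sum(n, arma::fill::zeros);
  arma::ivec oob_cnt(n, arma::fill::zeros);
  const int p = (int)X.n_cols;
  arma::vec imp(p, arma::fill::zeros);
  arma::ivec imp_cnt(p, arma::fill::zeros);

  std::vector<int> rows(n);
  std::vector<char> inbag(n);
  std::vector<int> oob_rows;
  oob_rows.reserve(n);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      rows[i] = k;
      inbag[k] = 1;
    }
    Tree tr;
    grow_node(tr, X, y, rows, 0, n, mtry, min_leaf);

    oob_rows.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob_rows.push_back(i);

    if (!oob_rows.empty()) {
      arma::vec pred_oob(oob_rows.size());
      double mse0 = 0.0;
      for (size_t i = 0; i < oob_rows.size(); ++i) {
        pred_oob[i] = predict_tree(tr, X, oob_rows[i]);
        const double e = pred_oob[i] - y[oob_rows[i]];
        mse0 += e * e;
        oob_sum[oob_rows[i]] += pred_oob[i];
        oob_cnt[oob_rows[i]] += 1;
      }
      mse0 /= oob_rows.size();

      if (importance) {
        const int no = (int)oob_rows.size();
        std::vector<int> perm(no);
        arma::rowvec xrow(p);
        for (int f = 0; f < p; ++f) {
          for (int i = 0; i < no; ++i) perm[i] = i;
          for (int i = no - 1; i > 0; --i) {
            int k = (int)(unif_rand() * (i + 1));
            if (k > i) k = i;
            std::swap(perm[i], perm[k]);
          }
          double mse1 = 0.0;
          for (int i = 0; i < no; ++i) {
            xrow = X.row(oob_rows[i]);
            xrow[f] = X(oob_rows[perm[i]], f);
            const double e = predict_tree_vec(tr, xrow) - y[oob_rows[i]];
            mse1 += e * e;
          }
          mse1 /= no;
          imp[f] += mse1 - mse0;
          imp_cnt[f] += 1;
        }
      }
    }

    trees[t] = List::create(_["feature"] = tr.feature,
                            _["threshold"] = tr.threshold,
                            _["left"] = tr.left, _["right"] = tr.right,
                            _["value"] = tr.value);
  }

  for (int f = 0; f < p; ++f)
    if (imp_cnt[f] > 0) imp[f] /= imp_cnt[f];
  arma::vec oob_pred(n);
  for (int i = 0; i < n; ++i)
    oob_pred[i] = oob_cnt[i] > 0 ? oob_sum[i] / oob_cnt[i] : NA_REAL;

  return List::create(_["trees"] = trees, _["oob_prediction"] = oob_pred,
                      _["importance"] = imp);
}

// [[Rcpp::export(name = ".cpp_forest_predict")]]
arma::vec cpp_forest_predict(const List &trees, const arma::mat &X) {
  const int n = (int)X.n_rows;
  const int T = trees.size();
  std::vector<Tree> trs(T);
  for (int t = 0; t < T; ++t) trs[t] = tree_from_list(trees[t]);
  arma::vec out(n, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i) out[i] += predict_tree(trs[t], X, i);
  return out / T;
}

// [[Rcpp::export(name = ".cpp_forest_predict_per_tree")]]
arma::mat cpp_forest_predict_per_tree(const List &trees, const arma::mat &X) {
  const int n = (int)X.n_rows;
  const int T = trees.size();
  arma::mat out(n, T);
  for (int t = 0; t < T; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out(i, t) = predict_tree(tr, X, i);
  }
  return out;
}
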