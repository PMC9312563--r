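// Binary-class random forest (CART trees, Gini split criterion, bootstrap
// bagging, per-node random feature subsets). Written against a fixed
// std::mt19937 stream so fits are reproducible across platforms
// independently of R's RNG.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Forest {
  // node-array representation, one set of vectors per tree
  std::vector<std::vector<int>> feat;     // split feature, -1 for leaf
  std::vector<std::vector<double>> thr;   // split threshold (x <= thr -> left)
  std::vector<std::vector<int>> left, right;
  std::vector<std::vector<double>> prob;  // leaf class-1 fraction
};

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node, n_feat;
  std::mt19937& rng;
  std::vector<double>& imp;  // gini importance accumulator
  std::vector<int> feat;
  std::vector<double> thr, prob;
  std::vector<int> left, right;

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
         int min_node_, std::mt19937& rng_, std::vector<double>& imp_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), n_feat(X_.ncol()),
        rng(rng_), imp(imp_) {}

  int make_leaf(const std::vector<int>& rows) {
    int n1 = 0;
    for (int r : rows) n1 += y[r];
    feat.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    prob.push_back(rows.empty() ? 0.5 : (double)n1 / rows.size());
    return (int)feat.size() - 1;
  }

  // returns node index
  int grow(const std::vector<int>& rows) {
    int n = (int)rows.size(), n1 = 0;
    for (int r : rows) n1 += y[r];
    if (n1 == 0 || n1 == n || n < 2 * min_node) return make_leaf(rows);

    // sample mtry features without replacement (partial Fisher-Yates)
    std::vector<int> fidx(n_feat);
    for (int j = 0; j < n_feat; ++j) fidx[j] = j;
    int m = std::min(mtry, n_feat);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, n_feat - 1);
      std::swap(fidx[j], fidx[d(rng)]);
    }

    double parent_imp = (double)n1 * (n - n1) / n;  // n * gini / 2
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int>> vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int j = fidx[jj];
      for (int i = 0; i < n; ++i)
        vals[i] = {X(rows[i], j), y[rows[i]]};
      std::sort(vals.begin(), vals.end());
      int c1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        c1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double child_imp = (double)c1 * (nl - c1) / nl +
                           (double)(n1 - c1) * (nr - (n1 - c1)) / nr;
        double gain = parent_imp - child_imp;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = j;
          best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
        }
      }
    }
    if (best_f < 0) return make_leaf(rows);

    std::vector<int> lrows, rrows;
    for (int r : rows)
      (X(r, best_f) <= best_thr ? lrows : rrows).push_back(r);
    imp[best_f] += best_gain;

    int self = (int)feat.size();
    feat.push_back(best_f);
    thr.push_back(best_thr);
    left.push_back(-1);
    right.push_back(-1);
    prob.push_back((double)n1 / n);
    int l = grow(lrows);
    int r = grow(rrows);
    left[self] = l;
    right[self] = r;
    return self;
  }
};

double predict_tree(const std::vector<int>& feat, const std::vector<double>& thr,
                    const std::vector<int>& left, const std::vector<int>& right,
                    const std::vector<double>& prob, const double* x,
                    R_xlen_t stride) {
  int node = 0;
  while (feat[node] >= 0)
    node = (x[feat[node] * stride] <= thr[node]) ? left[node] : right[node];
  return prob[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, int seed, bool permutation_importance) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);

  Forest forest;
  std::vector<double> imp(p, 0.0);
  std::vector<std::vector<int>> oob_rows(ntree);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> rows(n);
    std::vector<char> inbag(n, 0);
    for (int i = 0; i < n; ++i) {
      rows[i] = boot(rng);
      inbag[rows[i]] = 1;
    }
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob_rows[t].push_back(i);
    Grower g(X, y, mtry, min_node, rng, imp);
    g.grow(rows);
    forest.feat.push_back(std::move(g.feat));
    forest.thr.push_back(std::move(g.thr));
    forest.left.push_back(std::move(g.left));
    forest.right.push_back(std::move(g.right));
    forest.prob.push_back(std::move(g.prob));
  }
  for (int j = 0; j < p; ++j) imp[j] /= ntree;

  // OOB votes (class-1 probability averaged over trees where row is OOB)
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<double> xrow(p);
  for (int t = 0; t < ntree; ++t)
    for (int i : oob_rows[t]) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      oob_sum[i] += predict_tree(forest.feat[t], forest.thr[t], forest.left[t],
                                 forest.right[t], forest.prob[t], xrow.data(), 1);
      oob_cnt[i]++;
    }
  NumericVector oob(n);
  for (int i = 0; i < n; ++i)
    oob[i] = oob_cnt[i] ? oob_sum[i] / oob_cnt[i] : NA_REAL;

  NumericVector perm_imp(p, NA_REAL);
  if (permutation_importance) {
    // mean decrease in OOB accuracy after permuting each feature
    auto oob_acc = [&](int jperm, const std::vector<int>& permmap) {
      double correct = 0; int total = 0;
      std::vector<double> xr(p);
      for (int t = 0; t < ntree; ++t)
        for (size_t k = 0; k < oob_rows[t].size(); ++k) {
          int i = oob_rows[t][k];
          for (int j = 0; j < p; ++j) xr[j] = X(i, j);
          if (jperm >= 0) {
            int src = oob_rows[t][permmap[k] % oob_rows[t].size()];
            xr[jperm] = X(src, jperm);
          }
          double pr = predict_tree(forest.feat[t], forest.thr[t],
                                   forest.left[t], forest.right[t],
                                   forest.prob[t], xr.data(), 1);
          correct += ((pr >= 0.5) == (y[i] == 1));
          total++;
        }
      return total ? correct / total : NA_REAL;
    };
    std::vector<int> permmap(n);
    double base = oob_acc(-1, permmap);
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) permmap[i] = i;
      std::shuffle(permmap.begin(), permmap.end(), rng);
      perm_imp[j] = base - oob_acc(j, permmap);
    }
  }

  NumericVector importance(imp.begin(), imp.end());
  XPtr<Forest> ptr(new Forest(std::move(forest)), true);
  return List::create(_["importance"] = importance,
                      _["permutation_importance"] = perm_imp,
                      _["oob_prob"] = oob,
                      _["forest"] = ptr,
                      _["ntree"] = ntree, _["mtry"] = mtry);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(SEXP forest_ptr, NumericMatrix Xtest) {
  XPtr<Forest> f(forest_ptr);
  int n = Xtest.nrow(), p = Xtest.ncol();
  int ntree = (int)f->feat.size();
  NumericVector out(n);
  std::vector<double> xrow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = Xtest(i, j);
    double s = 0;
    for (int t = 0; t < ntree; ++t)
      s += predict_tree(f->feat[t], f->thr[t], f->left[t], f->right[t],
                        f->prob[t], xrow.data(), 1);
    out[i] = s / ntree;
  }
  return out;
}
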