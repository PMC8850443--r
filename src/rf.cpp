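// Compact random-forest regressor: bagged CART trees with variance-reduction
// splits and per-node feature subsampling. Deterministic given `seed`.
// Kept self-contained because the deployment image ships no forest package.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  // flat arrays; split_var == -1 marks a leaf
  std::vector<int> split_var, left, right;
  std::vector<double> split_val, value;

  int new_node() {
    split_var.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    split_val.push_back(0.0);
    value.push_back(0.0);
    return (int)split_var.size() - 1;
  }
};

struct WorkItem {
  int node;
  std::vector<int> idx; // row indices of the bootstrap sample in this node
};

// groups: one entry per predictor, listing its design-matrix columns.
// A categorical predictor expands to several one-hot columns but counts as
// a single draw in the mtry subsample, matching Breiman-forest semantics.
void grow_tree(const NumericMatrix& x, const NumericVector& y,
               const std::vector<int>& boot,
               const std::vector<std::vector<int>>& groups,
               int mtry, int min_node, std::mt19937& rng, Tree& tree) {
  const int p = (int)groups.size();
  std::vector<int> feat(p);
  for (int j = 0; j < p; ++j) feat[j] = j;

  std::vector<WorkItem> stack;
  int root = tree.new_node();
  stack.push_back({root, boot});

  while (!stack.empty()) {
    WorkItem w = std::move(stack.back());
    stack.pop_back();
    const std::vector<int>& idx = w.idx;
    const int n = (int)idx.size();

    double sum = 0.0, sum2 = 0.0;
    for (int i : idx) { sum += y[i]; sum2 += y[i] * y[i]; }
    const double mean = sum / n;
    tree.value[w.node] = mean;
    const double sse = sum2 - sum * sum / n;
    if (n < 2 * min_node || sse <= 1e-12) continue; // leaf

    // sample mtry candidate predictors without replacement (partial shuffle)
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(feat[j], feat[pick(rng)]);
    }
    std::vector<int> cand_cols;
    for (int j = 0; j < mtry; ++j) {
      for (int c : groups[feat[j]]) cand_cols.push_back(c);
    }

    int best_var = -1;
    double best_gain = 1e-12, best_thr = 0.0;
    std::vector<int> ord(idx);

    for (size_t jc = 0; jc < cand_cols.size(); ++jc) {
      const int v = cand_cols[jc];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return x(a, v) < x(b, v);
      });
      double lsum = 0.0;
      int nl = 0;
      for (int k = 0; k < n - 1; ++k) {
        lsum += y[ord[k]];
        ++nl;
        if (x(ord[k], v) == x(ord[k + 1], v)) continue; // not a valid cut
        if (nl < min_node || n - nl < min_node) continue;
        const double rsum = sum - lsum;
        const double gain = lsum * lsum / nl + rsum * rsum / (n - nl)
          - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_var = v;
          best_thr = 0.5 * (x(ord[k], v) + x(ord[k + 1], v));
        }
      }
    }
    if (best_var < 0) continue; // no admissible split

    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    for (int i : idx) {
      if (x(i, best_var) <= best_thr) lidx.push_back(i); else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) continue;

    tree.split_var[w.node] = best_var;
    tree.split_val[w.node] = best_thr;
    int ln = tree.new_node();
    int rn = tree.new_node();
    tree.left[w.node] = ln;
    tree.right[w.node] = rn;
    stack.push_back({ln, std::move(lidx)});
    stack.push_back({rn, std::move(ridx)});
  }
}

double predict_one(const Tree& t, const NumericMatrix& x, int row) {
  int node = 0;
  while (t.split_var[node] >= 0) {
    node = (x(row, t.split_var[node]) <= t.split_val[node])
      ? t.left[node] : t.right[node];
  }
  return t.value[node];
}

List pack_tree(const Tree& t) {
  return List::create(_["split_var"] = wrap(t.split_var),
                      _["split_val"] = wrap(t.split_val),
                      _["left"] = wrap(t.left),
                      _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

Tree unpack_tree(const List& l) {
  Tree t;
  t.split_var = as<std::vector<int>>(l["split_var"]);
  t.split_val = as<std::vector<double>>(l["split_val"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.value = as<std::vector<double>>(l["value"]);
  return t;
}

} // namespace

// [[Rcpp::export(rng = false)]]
List rf_fit_cpp(NumericMatrix x, NumericVector y, int num_trees, int mtry,
                int min_node, int seed, IntegerVector col_group) {
  const int n = x.nrow();
  if (y.size() != n) stop("x and y dimensions disagree");
  if (n < 2) stop("need at least 2 training rows");
  if (col_group.size() != x.ncol()) stop("col_group length must match ncol(x)");
  int n_groups = 0;
  for (int j = 0; j < col_group.size(); ++j) {
    if (col_group[j] < 0) stop("negative group id");
    n_groups = std::max(n_groups, col_group[j] + 1);
  }
  std::vector<std::vector<int>> groups(n_groups);
  for (int j = 0; j < col_group.size(); ++j) groups[col_group[j]].push_back(j);
  for (const auto& g : groups) {
    if (g.empty()) stop("empty predictor group");
  }
  if (mtry < 1 || mtry > n_groups) stop("invalid mtry");

  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> draw(0, n - 1);

  List trees(num_trees);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_n(n, 0);
  std::vector<char> inbag(n);

  for (int b = 0; b < num_trees; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) {
      boot[i] = draw(rng);
      inbag[boot[i]] = 1;
    }
    Tree t;
    grow_tree(x, y, boot, groups, mtry, min_node, rng, t);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_sum[i] += predict_one(t, x, i);
        ++oob_n[i];
      }
    }
    trees[b] = pack_tree(t);
  }

  NumericVector oob_pred(n, NA_REAL);
  double oob_sse = 0.0;
  int oob_cnt = 0;
  double ybar = mean(y);
  double tss = 0.0;
  for (int i = 0; i < n; ++i) {
    if (oob_n[i] > 0) {
      oob_pred[i] = oob_sum[i] / oob_n[i];
      const double e = oob_pred[i] - y[i];
      oob_sse += e * e;
      tss += (y[i] - ybar) * (y[i] - ybar);
      ++oob_cnt;
    }
  }
  const double oob_r2 = (oob_cnt > 1 && tss > 0.0)
    ? 1.0 - oob_sse / tss : NA_REAL;

  return List::create(_["trees"] = trees,
                      _["oob_pred"] = oob_pred,
                      _["oob_r2"] = oob_r2,
                      _["num_trees"] = num_trees,
                      _["mtry"] = mtry,
                      _["min_node"] = min_node,
                      _["n_train"] = n);
}

// [[Rcpp::export(rng = false)]]
NumericVector rf_predict_cpp(List forest, NumericMatrix x) {
  List trees = forest["trees"];
  const int B = trees.size();
  const int n = x.nrow();
  NumericVector out(n, 0.0);
  for (int b = 0; b < B; ++b) {
    Tree t = unpack_tree(trees[b]);
    for (int i = 0; i < n; ++i) out[i] += predict_one(t, x, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
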