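// Gradient-boosted regression trees (squared loss) with L1/L2 leaf
// regularization, row/column subsampling and early stopping, plus exact
// path-dependent tree-Shapley values.  Self-contained because no boosting
// library ships with the target environment.
//
// Training uses per-feature presorted row orders partitioned down the tree
// (no per-node sorting).  Shapley values come in two routes: the
// polynomial-time path algorithm used in production, and a brute-force
// subset enumeration over each tree's used features kept as an independent
// oracle for the tests.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;    // split feature, -1 for leaf
  std::vector<double> thr;     // go left when x < thr
  std::vector<int> left, right;
  std::vector<double> value;   // leaf value (learning rate folded in)
  std::vector<double> cover;   // sum of hessians reaching the node
};

inline double soft_threshold(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

inline double leaf_score(double G, double H, double alpha, double lambda) {
  const double t = soft_threshold(G, alpha);
  return t * t / (H + lambda);
}

inline double leaf_weight(double G, double H, double alpha, double lambda) {
  return -soft_threshold(G, alpha) / (H + lambda);
}

struct BuildCtx {
  const double* X;             // column-major n x p
  int n, p;
  const std::vector<double>* g;
  const std::vector<double>* h;
  double alpha, lambda, gamma, min_child_weight;
  int max_depth;
  double eta;
  const std::vector<int>* feats;  // candidate features for this tree
};

// rows of the node, presorted by each candidate feature (same multiset)
typedef std::vector<std::vector<int> > NodeOrders;

int grow(Tree& tree, BuildCtx& ctx, NodeOrders& orders, int depth) {
  const std::vector<int>& any = orders[0];
  double G = 0.0, H = 0.0;
  for (int r : any) { G += (*ctx.g)[r]; H += (*ctx.h)[r]; }

  const int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.thr.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(ctx.eta * leaf_weight(G, H, ctx.alpha, ctx.lambda));
  tree.cover.push_back(H);

  if (depth >= ctx.max_depth || (int)any.size() < 2) return node;

  const double parent_score = leaf_score(G, H, ctx.alpha, ctx.lambda);
  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1, best_k = -1;

  for (size_t fi = 0; fi < ctx.feats->size(); ++fi) {
    const int f = (*ctx.feats)[fi];
    const double* col = ctx.X + (size_t)f * ctx.n;
    const std::vector<int>& ord = orders[fi];
    double GL = 0.0, HL = 0.0;
    for (size_t i = 0; i + 1 < ord.size(); ++i) {
      GL += (*ctx.g)[ord[i]];
      HL += (*ctx.h)[ord[i]];
      if (col[ord[i]] == col[ord[i + 1]]) continue;  // not a valid cut
      const double HR = H - HL;
      if (HL < ctx.min_child_weight || HR < ctx.min_child_weight) continue;
      const double GR = G - GL;
      const double gain = 0.5 * (leaf_score(GL, HL, ctx.alpha, ctx.lambda) +
                                 leaf_score(GR, HR, ctx.alpha, ctx.lambda) -
                                 parent_score) - ctx.gamma;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = (int)fi;
        best_thr = 0.5 * (col[ord[i]] + col[ord[i + 1]]);
      }
    }
  }
  (void)best_k;
  if (best_feat < 0) return node;

  const double* split_col = ctx.X + (size_t)(*ctx.feats)[best_feat] * ctx.n;
  NodeOrders lorders(orders.size()), rorders(orders.size());
  for (size_t fi = 0; fi < orders.size(); ++fi) {
    lorders[fi].reserve(orders[fi].size());
    rorders[fi].reserve(orders[fi].size());
    for (int r : orders[fi])
      (split_col[r] < best_thr ? lorders[fi] : rorders[fi]).push_back(r);
    orders[fi].clear();
    orders[fi].shrink_to_fit();
  }

  tree.feature[node] = (*ctx.feats)[best_feat];
  tree.thr[node] = best_thr;
  tree.left[node] = grow(tree, ctx, lorders, depth + 1);
  tree.right[node] = grow(tree, ctx, rorders, depth + 1);
  return node;
}

double tree_predict_one(const Tree& t, const double* xcols, int n, int row) {
  int node = 0;
  while (t.feature[node] >= 0) {
    const double x = xcols[(size_t)t.feature[node] * n + row];
    node = (x < t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.value[node];
}

List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature), _["thr"] = wrap(t.thr),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value), _["cover"] = wrap(t.cover));
}

Tree tree_from_list(const List& l) {
  Tree t;
  t.feature = as<std::vector<int> >(l["feature"]);
  t.thr = as<std::vector<double> >(l["thr"]);
  t.left = as<std::vector<int> >(l["left"]);
  t.right = as<std::vector<int> >(l["right"]);
  t.value = as<std::vector<double> >(l["value"]);
  t.cover = as<std::vector<double> >(l["cover"]);
  return t;
}

// sample k of n indices without replacement using R's RNG (seedable from R)
std::vector<int> sample_idx(int n, int k) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(idx[i], idx[j]);
  }
  idx.resize(k);
  return idx;
}

double rmse_of(const std::vector<double>& pred, const NumericVector& y) {
  double s = 0.0;
  const int n = y.size();
  for (int i = 0; i < n; ++i) { const double d = pred[i] - y[i]; s += d * d; }
  return std::sqrt(s / n);
}

int ntree_limit_of(const List& model) {
  List trees = model["trees"];
  int ntree = trees.size();
  const int limit = as<int>(model["best_iter"]);
  if (limit > 0 && limit < ntree) ntree = limit;
  return ntree;
}

}  // namespace

// [[Rcpp::export(name = ".gbt_train_cpp")]]
List gbt_train_cpp(NumericMatrix X, NumericVector y, NumericMatrix Xval,
                   NumericVector yval, int nrounds, int max_depth, double eta,
                   double subsample, double colsample, double alpha,
                   double lambda, double gamma, double min_child_weight,
                   int early_stopping) {
  const int n = X.nrow(), p = X.ncol();
  const int nval = Xval.nrow();
  double base = 0.0;
  for (int i = 0; i < n; ++i) base += y[i];
  base /= n;

  // presort rows by every feature once per fit
  std::vector<std::vector<int> > presort(p, std::vector<int>(n));
  for (int f = 0; f < p; ++f) {
    const double* col = X.begin() + (size_t)f * n;
    std::vector<int>& ord = presort[f];
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<double> pred(n, base), predval(nval, base);
  std::vector<double> g(n), h(n, 1.0);
  std::vector<char> in_sample(n, 1);
  List trees(nrounds);
  NumericVector eval_log(nrounds, NA_REAL);
  double best_rmse = R_PosInf;
  int best_iter = 0, used = 0;

  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) g[i] = pred[i] - y[i];

    if (subsample < 1.0) {
      std::fill(in_sample.begin(), in_sample.end(), 0);
      const int k = std::max(1, (int)std::floor(subsample * n));
      for (int r : sample_idx(n, k)) in_sample[r] = 1;
    }
    std::vector<int> feats;
    if (colsample < 1.0) {
      const int k = std::max(1, (int)std::floor(colsample * p + 0.5));
      feats = sample_idx(p, k);
    } else {
      feats.resize(p);
      for (int j = 0; j < p; ++j) feats[j] = j;
    }

    NodeOrders orders(feats.size());
    for (size_t fi = 0; fi < feats.size(); ++fi) {
      const std::vector<int>& ord = presort[feats[fi]];
      std::vector<int>& dst = orders[fi];
      if (subsample < 1.0) {
        dst.reserve((size_t)(subsample * n) + 1);
        for (int r : ord) if (in_sample[r]) dst.push_back(r);
      } else dst = ord;
    }

    Tree tree;
    BuildCtx ctx;
    ctx.X = X.begin(); ctx.n = n; ctx.p = p; ctx.g = &g; ctx.h = &h;
    ctx.alpha = alpha; ctx.lambda = lambda; ctx.gamma = gamma;
    ctx.min_child_weight = min_child_weight; ctx.max_depth = max_depth;
    ctx.eta = eta; ctx.feats = &feats;
    grow(tree, ctx, orders, 0);

    for (int i = 0; i < n; ++i) pred[i] += tree_predict_one(tree, X.begin(), n, i);
    trees[round] = tree_to_list(tree);
    used = round + 1;

    if (nval > 0) {
      for (int i = 0; i < nval; ++i)
        predval[i] += tree_predict_one(tree, Xval.begin(), nval, i);
      const double r = rmse_of(predval, yval);
      eval_log[round] = r;
      if (r < best_rmse - 1e-12) { best_rmse = r; best_iter = round + 1; }
      if (early_stopping > 0 && round + 1 - best_iter >= early_stopping) break;
    } else {
      best_iter = round + 1;
    }
  }

  List out = List::create(
      _["trees"] = trees[Range(0, used - 1)], _["base"] = base,
      _["best_iter"] = best_iter, _["nrounds_used"] = used,
      _["eval_log"] = eval_log[Range(0, used - 1)]);
  out.attr("class") = "gbt_model";
  return out;
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X, int ntree_limit) {
  const int n = X.nrow();
  List trees = model["trees"];
  const double base = as<double>(model["base"]);
  int ntree = trees.size();
  if (ntree_limit > 0 && ntree_limit < ntree) ntree = ntree_limit;
  NumericVector out(n, base);
  for (int k = 0; k < ntree; ++k) {
    Tree t = tree_from_list(trees[k]);
    for (int i = 0; i < n; ++i)
      out[i] += tree_predict_one(t, X.begin(), n, i);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Path-dependent TreeSHAP (polynomial time): maintains, along each root-leaf
// traversal, the weights of subset-permutation blocks for the unique features
// on the path.
// ---------------------------------------------------------------------------

namespace {

struct PathElement {
  int feature;
  double zero_fraction;  // proportion of paths flowing through when excluded
  double one_fraction;   // 1 when x follows the split, else 0
  double pweight;
};

void extend_path(PathElement* path, int depth, double zero_fraction,
                 double one_fraction, int feature) {
  path[depth].feature = feature;
  path[depth].zero_fraction = zero_fraction;
  path[depth].one_fraction = one_fraction;
  path[depth].pweight = depth == 0 ? 1.0 : 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1) /
      (double)(depth + 1);
    path[i].pweight = zero_fraction * path[i].pweight * (depth - i) /
      (double)(depth + 1);
  }
}

void unwind_path(PathElement* path, int depth, int index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one = path[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one * (depth + 1) /
        (double)((i + 1) * one_fraction);
      next_one = tmp - path[i].pweight * zero_fraction * (depth - i) /
        (double)(depth + 1);
    } else {
      path[i].pweight = path[i].pweight * (depth + 1) /
        (double)(zero_fraction * (depth - i));
    }
  }
  for (int i = index; i < depth; ++i) {
    path[i].feature = path[i + 1].feature;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement* path, int depth, int index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one = path[depth].pweight;
  double total = 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one * (depth + 1) /
        (double)((i + 1) * one_fraction);
      total += tmp;
      next_one = path[i].pweight - tmp * zero_fraction * (depth - i) /
        (double)(depth + 1);
    } else {
      total += path[i].pweight * (depth + 1) /
        (double)(zero_fraction * (depth - i));
    }
  }
  return total;
}

void shap_recurse(const Tree& t, int node, const double* xcols, int n,
                  int row, double* phi, PathElement* parent_path, int depth,
                  double parent_zero, double parent_one, int parent_feature) {
  PathElement* path = parent_path + depth + 1;
  std::memcpy(path, parent_path, (depth > 0 ? depth : 1) * sizeof(PathElement));
  extend_path(path, depth, parent_zero, parent_one, parent_feature);

  if (t.feature[node] < 0) {
    for (int i = 1; i <= depth; ++i) {
      const double w = unwound_path_sum(path, depth, i);
      phi[path[i].feature] +=
        w * (path[i].one_fraction - path[i].zero_fraction) * t.value[node];
    }
    return;
  }

  const int split = t.feature[node];
  const double x = xcols[(size_t)split * n + row];
  const int hot = x < t.thr[node] ? t.left[node] : t.right[node];
  const int cold = x < t.thr[node] ? t.right[node] : t.left[node];
  const double hot_zero = t.cover[hot] / t.cover[node];
  const double cold_zero = t.cover[cold] / t.cover[node];

  double incoming_zero = 1.0, incoming_one = 1.0;
  int k = 0;
  for (; k <= depth; ++k)
    if (path[k].feature == split) break;
  int d = depth;
  if (k <= depth) {
    incoming_zero = path[k].zero_fraction;
    incoming_one = path[k].one_fraction;
    unwind_path(path, d, k);
    d -= 1;
  }
  shap_recurse(t, hot, xcols, n, row, phi, path, d + 1,
               hot_zero * incoming_zero, incoming_one, split);
  shap_recurse(t, cold, xcols, n, row, phi, path, d + 1,
               cold_zero * incoming_zero, 0.0, split);
}

double tree_expected_value(const Tree& t, int node) {
  if (t.feature[node] < 0) return t.value[node];
  const int l = t.left[node], r = t.right[node];
  return (t.cover[l] * tree_expected_value(t, l) +
          t.cover[r] * tree_expected_value(t, r)) / t.cover[node];
}

}  // namespace

// [[Rcpp::export(name = ".gbt_shap_cpp")]]
List gbt_shap_cpp(List model, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  List trees = model["trees"];
  double base = as<double>(model["base"]);
  const int ntree = ntree_limit_of(model);

  NumericMatrix phi(n, p);
  std::vector<PathElement> buf;
  for (int k = 0; k < ntree; ++k) {
    Tree t = tree_from_list(trees[k]);
    int maxd = 0;
    {  // tree depth for buffer sizing
      std::vector<std::pair<int, int> > stack;
      stack.push_back(std::make_pair(0, 0));
      while (!stack.empty()) {
        std::pair<int, int> top = stack.back();
        stack.pop_back();
        maxd = std::max(maxd, top.second);
        if (t.feature[top.first] >= 0) {
          stack.push_back(std::make_pair(t.left[top.first], top.second + 1));
          stack.push_back(std::make_pair(t.right[top.first], top.second + 1));
        }
      }
    }
    buf.assign((size_t)(maxd + 2) * (maxd + 3), PathElement());
    base += tree_expected_value(t, 0);
    std::vector<double> row_phi(p);
    for (int i = 0; i < n; ++i) {
      std::fill(row_phi.begin(), row_phi.end(), 0.0);
      shap_recurse(t, 0, X.begin(), n, i, row_phi.data(), buf.data(), 0, 1.0,
                   1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += row_phi[j];
    }
  }
  // shift per-record sums so that base + rowSums(phi) = prediction: the
  // recursion attributes everything relative to the tree expectation, and
  // feature slots are column offsets of phi, so phi rows already sum to
  // prediction - expectation.
  return List::create(_["phi"] = phi, _["base"] = base);
}

// ---------------------------------------------------------------------------
// Brute-force Shapley oracle: enumerate all subsets of each tree's used
// features; v(S) descends the tree, averaging unknown splits by cover.
// Exponential in features-per-tree; test/reference use only.
// ---------------------------------------------------------------------------

namespace {

double expvalue(const Tree& t, int node, unsigned mask,
                const std::vector<int>& bitpos, const double* X, int n,
                int row) {
  while (true) {
    const int f = t.feature[node];
    if (f < 0) return t.value[node];
    if (bitpos[f] >= 0 && ((mask >> bitpos[f]) & 1u)) {
      const double x = X[(size_t)f * n + row];
      node = (x < t.thr[node]) ? t.left[node] : t.right[node];
    } else {
      const double cl = t.cover[t.left[node]], cr = t.cover[t.right[node]];
      return (cl * expvalue(t, t.left[node], mask, bitpos, X, n, row) +
              cr * expvalue(t, t.right[node], mask, bitpos, X, n, row)) /
             t.cover[node];
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".gbt_shap_brute_cpp")]]
List gbt_shap_brute_cpp(List model, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  List trees = model["trees"];
  double base = as<double>(model["base"]);
  const int ntree = ntree_limit_of(model);

  NumericMatrix phi(n, p);
  std::vector<double> factorials(33, 1.0);
  for (int i = 1; i < 33; ++i) factorials[i] = factorials[i - 1] * i;

  for (int k = 0; k < ntree; ++k) {
    Tree t = tree_from_list(trees[k]);
    std::vector<int> used;
    std::vector<int> bitpos(p, -1);
    for (size_t nd = 0; nd < t.feature.size(); ++nd) {
      const int f = t.feature[nd];
      if (f >= 0 && bitpos[f] < 0) {
        bitpos[f] = (int)used.size();
        used.push_back(f);
      }
    }
    const int m = (int)used.size();
    if (m == 0) { base += t.value[0]; continue; }
    if (m > 20) stop("tree uses too many features for brute-force Shapley");
    const unsigned nsub = 1u << m;
    std::vector<double> v(nsub);
    std::vector<int> popcount(nsub, 0);
    for (unsigned mask = 1; mask < nsub; ++mask)
      popcount[mask] = popcount[mask >> 1] + (mask & 1u);
    std::vector<double> w(m);
    for (int s = 0; s < m; ++s)
      w[s] = factorials[s] * factorials[m - s - 1] / factorials[m];

    double v_empty = 0.0;
    for (int i = 0; i < n; ++i) {
      for (unsigned mask = 0; mask < nsub; ++mask)
        v[mask] = expvalue(t, 0, mask, bitpos, X.begin(), n, i);
      if (i == 0) v_empty = v[0];
      for (int j = 0; j < m; ++j) {
        const unsigned bit = 1u << j;
        double ph = 0.0;
        for (unsigned mask = 0; mask < nsub; ++mask) {
          if (mask & bit) continue;
          ph += w[popcount[mask]] * (v[mask | bit] - v[mask]);
        }
        phi(i, used[j]) += ph;
      }
    }
    base += v_empty;
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}
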