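// Gradient-boosted regression trees with exact greedy splits, missing-value
// default directions, and early stopping on validation RMSE; plus the
// path-dependent TreeSHAP recursion for feature attribution.
//
// Loss: squared error (objective "regression") or logistic ("binary").
// Regularisation follows the XGBoost formulation: leaf value
// w = -G / (H + lambda); split gain
// 0.5 * (GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l)).
// Missing feature values (NA) are routed along a per-split default
// direction learned from the data. Splits are searched deterministically
// (features in column order, thresholds in ascending value order).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature = -1;        // -1 for a leaf
  double threshold = 0.0;  // go left if x < threshold
  bool default_left = true;
  int left = -1, right = -1;
  double value = 0.0;      // leaf weight
  double cover = 0.0;      // training rows reaching the node
};

struct Tree { std::vector<Node> nodes; };

struct BoostParams {
  double eta, lambda, min_child_weight;
  int max_depth;
};

static double node_score(double G, double H, double lambda) {
  return G * G / (H + lambda);
}

// grow one tree on rows `idx`, gradients g, hessians h
static int build_node(const NumericMatrix& X, const std::vector<double>& g,
                      const std::vector<double>& h, std::vector<int>& idx,
                      int depth, const BoostParams& P, Tree& tree) {
  double G = 0, H = 0;
  for (int r : idx) { G += g[r]; H += h[r]; }
  int me = tree.nodes.size();
  tree.nodes.push_back(Node());
  tree.nodes[me].cover = idx.size();

  double best_gain = 0.0;
  int best_f = -1;
  double best_thr = 0.0;
  bool best_missing_left = true;
  double parent_score = node_score(G, H, P.lambda);

  if (depth < P.max_depth && idx.size() >= 2) {
    int nf = X.ncol();
    std::vector<std::pair<double, int> > vals;
    for (int f = 0; f < nf; ++f) {
      vals.clear();
      double Gm = 0, Hm = 0;  // missing-value totals
      for (int r : idx) {
        double x = X(r, f);
        if (ISNAN(x)) { Gm += g[r]; Hm += h[r]; }
        else vals.push_back(std::make_pair(x, r));
      }
      if (vals.size() < 2) continue;
      std::sort(vals.begin(), vals.end());
      double GL = 0, HL = 0;
      double Gp = G - Gm, Hp = H - Hm;  // present totals
      for (size_t q = 0; q + 1 < vals.size(); ++q) {
        GL += g[vals[q].second]; HL += h[vals[q].second];
        if (vals[q + 1].first == vals[q].first) continue;
        double thr = (vals[q].first + vals[q + 1].first) / 2.0;
        // missing left
        {
          double gl = GL + Gm, hl = HL + Hm;
          double gr = G - gl, hr = H - hl;
          if (hl >= P.min_child_weight && hr >= P.min_child_weight) {
            double gain = 0.5 * (node_score(gl, hl, P.lambda) +
                                 node_score(gr, hr, P.lambda) - parent_score);
            if (gain > best_gain + 1e-12) {
              best_gain = gain; best_f = f; best_thr = thr;
              best_missing_left = true;
            }
          }
        }
        // missing right
        {
          double gl = GL, hl = HL;
          double gr = (Gp - GL) + Gm, hr = (Hp - HL) + Hm;
          if (hl >= P.min_child_weight && hr >= P.min_child_weight) {
            double gain = 0.5 * (node_score(gl, hl, P.lambda) +
                                 node_score(gr, hr, P.lambda) - parent_score);
            if (gain > best_gain + 1e-12) {
              best_gain = gain; best_f = f; best_thr = thr;
              best_missing_left = false;
            }
          }
        }
      }
    }
  }

  if (best_f < 0) {  // leaf
    tree.nodes[me].value = -G / (H + P.lambda);
    return me;
  }
  std::vector<int> lidx, ridx;
  for (int r : idx) {
    double x = X(r, best_f);
    bool left = ISNAN(x) ? best_missing_left : (x < best_thr);
    (left ? lidx : ridx).push_back(r);
  }
  tree.nodes[me].feature = best_f;
  tree.nodes[me].threshold = best_thr;
  tree.nodes[me].default_left = best_missing_left;
  int l = build_node(X, g, h, lidx, depth + 1, P, tree);
  int r = build_node(X, g, h, ridx, depth + 1, P, tree);
  tree.nodes[me].left = l;
  tree.nodes[me].right = r;
  return me;
}

static double tree_predict(const Tree& t, const NumericMatrix& X, int row) {
  int q = 0;
  while (t.nodes[q].feature >= 0) {
    double x = X(row, t.nodes[q].feature);
    bool left = ISNAN(x) ? t.nodes[q].default_left
                         : (x < t.nodes[q].threshold);
    q = left ? t.nodes[q].left : t.nodes[q].right;
  }
  return t.nodes[q].value;
}

static List tree_to_list(const Tree& t) {
  int m = t.nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m), cover(m);
  LogicalVector defleft(m);
  for (int q = 0; q < m; ++q) {
    feature[q] = t.nodes[q].feature;
    threshold[q] = t.nodes[q].threshold;
    defleft[q] = t.nodes[q].default_left;
    left[q] = t.nodes[q].left;
    right[q] = t.nodes[q].right;
    value[q] = t.nodes[q].value;
    cover[q] = t.nodes[q].cover;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["default_left"] = defleft, _["left"] = left,
                      _["right"] = right, _["value"] = value,
                      _["cover"] = cover);
}

static Tree tree_from_list(const List& l) {
  IntegerVector feature = l["feature"], left = l["left"], right = l["right"];
  NumericVector threshold = l["threshold"], value = l["value"],
                cover = l["cover"];
  LogicalVector defleft = l["default_left"];
  Tree t;
  int m = feature.size();
  t.nodes.resize(m);
  for (int q = 0; q < m; ++q) {
    t.nodes[q].feature = feature[q];
    t.nodes[q].threshold = threshold[q];
    t.nodes[q].default_left = defleft[q];
    t.nodes[q].left = left[q];
    t.nodes[q].right = right[q];
    t.nodes[q].value = value[q];
    t.nodes[q].cover = cover[q];
  }
  return t;
}

// [[Rcpp::export(name = ".gbt_train")]]
List gbt_train(NumericMatrix X, NumericVector y, IntegerVector train_rows,
               IntegerVector val_rows, std::string objective, int max_rounds,
               int patience, double eta, double lambda,
               double min_child_weight, int max_depth) {
  BoostParams P;
  P.eta = eta; P.lambda = lambda; P.min_child_weight = min_child_weight;
  P.max_depth = max_depth;
  int n = X.nrow();
  bool binary = (objective == "binary");

  // base score: mean target (raw score for regression, log-odds for binary)
  double mu = 0;
  for (int r : train_rows) mu += y[r];
  mu /= train_rows.size();
  double base = binary ? std::log(std::max(mu, 1e-6) /
                                  std::max(1.0 - mu, 1e-6)) : mu;

  std::vector<double> f(n, base);
  std::vector<Tree> trees;
  std::vector<double> g(n), h(n);
  double best_rmse = R_PosInf;
  int best_iter = 0, since_best = 0;

  auto val_rmse = [&]() {
    double s = 0;
    for (int r : val_rows) {
      double p = binary ? 1.0 / (1.0 + std::exp(-f[r])) : f[r];
      s += (p - y[r]) * (p - y[r]);
    }
    return std::sqrt(s / val_rows.size());
  };

  for (int round = 0; round < max_rounds; ++round) {
    for (int r : train_rows) {
      if (binary) {
        double p = 1.0 / (1.0 + std::exp(-f[r]));
        g[r] = p - y[r];
        h[r] = std::max(p * (1.0 - p), 1e-16);
      } else {
        g[r] = f[r] - y[r];
        h[r] = 1.0;
      }
    }
    Tree t;
    std::vector<int> idx(train_rows.begin(), train_rows.end());
    build_node(X, g, h, idx, 0, P, t);
    for (int r = 0; r < n; ++r) f[r] += eta * tree_predict(t, X, r);
    trees.push_back(t);

    double rmse = val_rmse();
    if (rmse < best_rmse - 1e-12) {
      best_rmse = rmse;
      best_iter = round + 1;
      since_best = 0;
    } else if (++since_best >= patience) break;
  }

  List tl(best_iter);
  for (int q = 0; q < best_iter; ++q) tl[q] = tree_to_list(trees[q]);
  return List::create(_["base_score"] = base, _["trees"] = tl,
                      _["eta"] = eta, _["objective"] = objective,
                      _["best_val_rmse"] = best_rmse,
                      _["n_rounds"] = best_iter);
}

// [[Rcpp::export(name = ".gbt_predict")]]
NumericVector gbt_predict(List model, NumericMatrix X, bool raw = false) {
  double base = model["base_score"];
  double eta = model["eta"];
  std::string objective = as<std::string>(model["objective"]);
  List tl = model["trees"];
  int n = X.nrow();
  NumericVector out(n, base);
  for (int q = 0; q < tl.size(); ++q) {
    Tree t = tree_from_list(tl[q]);
    for (int r = 0; r < n; ++r) out[r] += eta * tree_predict(t, X, r);
  }
  if (objective == "binary" && !raw)
    for (int r = 0; r < n; ++r) out[r] = 1.0 / (1.0 + std::exp(-out[r]));
  return out;
}

// ----------------------------------------------------------------------
// TreeSHAP (path-dependent): Lundberg et al.'s polynomial-time algorithm.

struct PathElem {
  int feature;
  double zero_fraction, one_fraction, pweight;
};

static void shap_extend(std::vector<PathElem>& path, double pz, double po,
                        int pi) {
  int l = path.size();
  PathElem e; e.feature = pi; e.zero_fraction = pz; e.one_fraction = po;
  e.pweight = (l == 0) ? 1.0 : 0.0;
  path.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    path[i + 1].pweight += po * path[i].pweight * (i + 1) / double(l + 1);
    path[i].pweight = pz * path[i].pweight * (l - i) / double(l + 1);
  }
}

static void shap_unwind(std::vector<PathElem>& path, int pidx) {
  int l = path.size() - 1;
  double po = path[pidx].one_fraction, pz = path[pidx].zero_fraction;
  double next_one = path[l].pweight;
  for (int i = l - 1; i >= 0; --i) {
    if (po != 0) {
      double tmp = path[i].pweight;
      path[i].pweight = next_one * (l + 1) / ((i + 1) * po);
      next_one = tmp - path[i].pweight * pz * (l - i) / double(l + 1);
    } else {
      path[i].pweight = path[i].pweight * (l + 1) / (pz * (l - i));
    }
  }
  for (int i = pidx; i < l; ++i) {
    path[i].feature = path[i + 1].feature;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
  path.pop_back();
}

static double shap_unwound_sum(const std::vector<PathElem>& path, int pidx) {
  int l = path.size() - 1;
  double po = path[pidx].one_fraction, pz = path[pidx].zero_fraction;
  double next_one = path[l].pweight, total = 0;
  for (int i = l - 1; i >= 0; --i) {
    if (po != 0) {
      double tmp = next_one * (l + 1) / ((i + 1) * po);
      total += tmp;
      next_one = path[i].pweight - tmp * pz * (l - i) / double(l + 1);
    } else if (pz != 0) {
      total += (path[i].pweight / pz) * (l + 1) / double(l - i);
    }
  }
  return total;
}

static void shap_recurse(const Tree& t, const NumericMatrix& X, int row,
                         int node, std::vector<PathElem> path, double pz,
                         double po, int pfeature, std::vector<double>& phi) {
  shap_extend(path, pz, po, pfeature);
  const Node& nd = t.nodes[node];
  if (nd.feature < 0) {
    for (size_t i = 1; i < path.size(); ++i) {
      double w = shap_unwound_sum(path, i);
      phi[path[i].feature] +=
          w * (path[i].one_fraction - path[i].zero_fraction) * nd.value;
    }
    return;
  }
  double x = X(row, nd.feature);
  bool left = ISNAN(x) ? nd.default_left : (x < nd.threshold);
  int hot = left ? nd.left : nd.right;
  int cold = left ? nd.right : nd.left;
  double iz = 1, io = 1;
  for (size_t k = 1; k < path.size(); ++k) {
    if (path[k].feature == nd.feature) {
      iz = path[k].zero_fraction;
      io = path[k].one_fraction;
      shap_unwind(path, k);
      break;
    }
  }
  double cov = nd.cover;
  shap_recurse(t, X, row, hot, path, iz * t.nodes[hot].cover / cov, io,
               nd.feature, phi);
  shap_recurse(t, X, row, cold, path, iz * t.nodes[cold].cover / cov, 0.0,
               nd.feature, phi);
}

static double tree_expected(const Tree& t, int node) {
  const Node& nd = t.nodes[node];
  if (nd.feature < 0) return nd.value;
  double cl = t.nodes[nd.left].cover, cr = t.nodes[nd.right].cover;
  return (cl * tree_expected(t, nd.left) + cr * tree_expected(t, nd.right)) /
         (cl + cr);
}

// Returns n x (p + 1) matrix: per-feature attributions plus the expected
// value (bias) in the last column. Attributions are on the raw-score scale.
// [[Rcpp::export(name = ".gbt_shap")]]
NumericMatrix gbt_shap(List model, NumericMatrix X) {
  double base = model["base_score"];
  double eta = model["eta"];
  List tl = model["trees"];
  int n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p + 1);
  double bias = base;
  std::vector<Tree> trees(tl.size());
  for (int q = 0; q < tl.size(); ++q) trees[q] = tree_from_list(tl[q]);
  for (const Tree& t : trees) bias += eta * tree_expected(t, 0);
  for (int r = 0; r < n; ++r) {
    std::vector<double> phi(p, 0.0);
    for (const Tree& t : trees) {
      std::vector<PathElem> path;
      shap_recurse(t, X, r, 0, path, 1.0, 1.0, -1, phi);
    }
    for (int f = 0; f < p; ++f) out(r, f) = eta * phi[f];
    out(r, p) = bias;
  }
  return out;
}
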