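// Regularized second-order gradient boosting: exact greedy split search over
// midpoint thresholds, level-wise growth over globally presorted features.
// Leaf weight -G/(H+lambda); split gain  1/2[GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l)] - gamma.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, weight;
  std::vector<bool> is_leaf;
  int add_node() {
    feature.push_back(-1); threshold.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    weight.push_back(0.0); is_leaf.push_back(false);
    return (int)feature.size() - 1;
  }
};

const double GAIN_EPS = 1e-12;  // guards float noise from creating zero-gain splits

// Presort sample indices by each feature value (ties by index; tie order
// cannot affect splits because candidates only occur at value changes).
std::vector<std::vector<int>> presort(const NumericMatrix& X) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<std::vector<int>> ord(m, std::vector<int>(n));
  for (int j = 0; j < m; ++j) {
    std::vector<int>& o = ord[j];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, j);
    std::sort(o.begin(), o.end(), [col](int a, int b) {
      if (col[a] != col[b]) return col[a] < col[b];
      return a < b;
    });
  }
  return ord;
}

inline double leaf_w(double G, double H, double lambda) {
  const double den = H + lambda;
  return den > 0.0 ? -G / den : 0.0;
}

Tree grow_one(const NumericMatrix& X, const std::vector<std::vector<int>>& ord,
              const NumericVector& g, const NumericVector& h,
              int max_depth, double lambda, double gamma, double min_child_hessian) {
  const int n = X.nrow(), m = X.ncol();
  Tree tr;
  std::vector<double> nodeG, nodeH;
  std::vector<int> pos(n, 0);

  const int root = tr.add_node();
  double G0 = 0.0, H0 = 0.0;
  for (int i = 0; i < n; ++i) { G0 += g[i]; H0 += h[i]; }
  nodeG.push_back(G0); nodeH.push_back(H0);

  std::vector<int> active(1, root);

  for (int depth = 0; depth < max_depth && !active.empty(); ++depth) {
    const int na = (int)active.size();
    std::vector<int> slot_of(tr.feature.size(), -1);
    for (int s = 0; s < na; ++s) slot_of[active[s]] = s;

    std::vector<double> bestGain(na, 0.0), bestThr(na, 0.0);
    std::vector<double> bestGL(na, 0.0), bestHL(na, 0.0);
    std::vector<int> bestFeat(na, -1);

    std::vector<double> GL(na), HL(na), lastVal(na);
    std::vector<char> hasPrev(na);

    const double* xbase = &X(0, 0);
    const double* gp = &g[0];
    const double* hp = &h[0];
    for (int j = 0; j < m; ++j) {
      std::fill(GL.begin(), GL.end(), 0.0);
      std::fill(HL.begin(), HL.end(), 0.0);
      std::fill(hasPrev.begin(), hasPrev.end(), 0);
      const std::vector<int>& o = ord[j];
      const double* col = xbase + (size_t)j * n;
      for (int t = 0; t < n; ++t) {
        const int i = o[t];
        const int nd = pos[i];
        if (nd < 0) continue;
        const int s = slot_of[nd];
        if (s < 0) continue;
        const double v = col[i];
        if (hasPrev[s] && v > lastVal[s]) {
          const double gl = GL[s], hl = HL[s];
          const double gr = nodeG[nd] - gl, hr = nodeH[nd] - hl;
          if (hl >= min_child_hessian && hr >= min_child_hessian &&
              hl + lambda > 0.0 && hr + lambda > 0.0) {
            const double gain =
              0.5 * (gl * gl / (hl + lambda) + gr * gr / (hr + lambda) -
                     nodeG[nd] * nodeG[nd] / (nodeH[nd] + lambda)) - gamma;
            if (gain > bestGain[s] + GAIN_EPS) {  // strict: ties keep the
                                                  // earliest (feature, threshold)
              bestGain[s] = gain;
              bestFeat[s] = j;
              bestThr[s] = 0.5 * (lastVal[s] + v);
              bestGL[s] = gl; bestHL[s] = hl;
            }
          }
        }
        GL[s] += gp[i]; HL[s] += hp[i];
        lastVal[s] = v; hasPrev[s] = 1;
      }
    }

    std::vector<int> next_active;
    std::vector<char> splitting(na, 0);
    for (int s = 0; s < na; ++s) {
      const int nd = active[s];
      if (bestFeat[s] >= 0 && bestGain[s] > GAIN_EPS) {
        splitting[s] = 1;
        tr.feature[nd] = bestFeat[s];
        tr.threshold[nd] = bestThr[s];
        const int l = tr.add_node();
        const int r = tr.add_node();
        slot_of.resize(tr.feature.size(), -1);
        tr.left[nd] = l; tr.right[nd] = r;
        nodeG.push_back(bestGL[s]); nodeH.push_back(bestHL[s]);
        nodeG.push_back(nodeG[nd] - bestGL[s]); nodeH.push_back(nodeH[nd] - bestHL[s]);
        next_active.push_back(l); next_active.push_back(r);
      } else {
        tr.is_leaf[nd] = true;
        tr.weight[nd] = leaf_w(nodeG[nd], nodeH[nd], lambda);
      }
    }
    for (int i = 0; i < n; ++i) {
      const int nd = pos[i];
      if (nd < 0) continue;
      const int s = slot_of[nd];
      if (s < 0 || s >= na) continue;
      if (splitting[s])
        pos[i] = X(i, tr.feature[nd]) < tr.threshold[nd] ? tr.left[nd] : tr.right[nd];
      else
        pos[i] = -1;
    }
    active.swap(next_active);
  }
  for (int nd : active) {  // depth cap reached
    tr.is_leaf[nd] = true;
    tr.weight[nd] = leaf_w(nodeG[nd], nodeH[nd], lambda);
  }
  return tr;
}

List tree_to_list(const Tree& tr) {
  const int nn = (int)tr.feature.size();
  IntegerVector feature(nn), left(nn), right(nn);
  NumericVector threshold(nn), weight(nn);
  LogicalVector is_leaf(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = tr.feature[i]; left[i] = tr.left[i]; right[i] = tr.right[i];
    threshold[i] = tr.threshold[i]; weight[i] = tr.weight[i]; is_leaf[i] = tr.is_leaf[i];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["weight"] = weight, _["is_leaf"] = is_leaf);
}

void add_tree_margins(const Tree& tr, const NumericMatrix& X,
                      std::vector<double>& margin, double scale) {
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int nd = 0;
    while (!tr.is_leaf[nd])
      nd = X(i, tr.feature[nd]) < tr.threshold[nd] ? tr.left[nd] : tr.right[nd];
    margin[i] += scale * tr.weight[nd];
  }
}

} // namespace

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, NumericVector g, NumericVector h,
                   int max_depth, double lambda, double gamma,
                   double min_child_hessian) {
  if (g.size() != X.nrow() || h.size() != X.nrow())
    stop("g/h length must equal nrow(X)");
  std::vector<std::vector<int>> ord = presort(X);
  Tree tr = grow_one(X, ord, g, h, max_depth, lambda, gamma, min_child_hessian);
  return tree_to_list(tr);
}

// [[Rcpp::export(name = ".fit_gbt_cpp")]]
List fit_gbt_cpp(NumericMatrix X, NumericVector y, int nrounds, int max_depth,
                 double eta, double lambda, double gamma,
                 double min_child_hessian, double scale_pos_weight,
                 double base_margin, bool logistic) {
  const int n = X.nrow();
  if (y.size() != n) stop("y length must equal nrow(X)");
  std::vector<std::vector<int>> ord = presort(X);
  std::vector<double> margin(n, base_margin);
  NumericVector g(n), h(n);
  List trees(nrounds);
  for (int k = 0; k < nrounds; ++k) {
    for (int i = 0; i < n; ++i) {
      const double w = (y[i] == 1.0) ? scale_pos_weight : 1.0;
      if (logistic) {
        const double p = 1.0 / (1.0 + std::exp(-margin[i]));
        g[i] = w * (p - y[i]);
        h[i] = w * p * (1.0 - p);
      } else {
        g[i] = w * (margin[i] - y[i]);
        h[i] = w;
      }
    }
    Tree tr = grow_one(X, ord, g, h, max_depth, lambda, gamma, min_child_hessian);
    // shrinkage folded into stored leaf weights
    for (size_t nd = 0; nd < tr.weight.size(); ++nd)
      if (tr.is_leaf[nd]) tr.weight[nd] *= eta;
    add_tree_margins(tr, X, margin, 1.0);
    trees[k] = tree_to_list(tr);
  }
  return List::create(_["trees"] = trees, _["base_margin"] = base_margin);
}

// [[Rcpp::export(name = ".predict_margin_cpp")]]
NumericVector predict_margin_cpp(List trees, NumericMatrix X, double base_margin) {
  const int n = X.nrow();
  NumericVector out(n, base_margin);
  for (int k = 0; k < trees.size(); ++k) {
    List tree = trees[k];
    IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
    NumericVector threshold = tree["threshold"], weight = tree["weight"];
    LogicalVector is_leaf = tree["is_leaf"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (!is_leaf[nd])
        nd = X(i, feature[nd]) < threshold[nd] ? left[nd] : right[nd];
      out[i] += weight[nd];
    }
  }
  return out;
}
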