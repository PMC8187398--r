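#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Depth-limited exact-greedy regression tree on squared error. Nodes are
// stored in flat arrays; feature == -1 marks a leaf. Split rule: x[f] <= thr
// goes left. Leaf *values* are filled in from R (boosting needs a custom
// leaf-value formula), so the builder returns structure plus the leaf index
// of every training sample.

struct Node {
  int feature = -1;
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
  int n = 0;
};

static void split_node(const NumericMatrix &X, const NumericVector &y,
                       std::vector<int> &idx, int depth, int max_depth,
                       int min_leaf, std::vector<Node> &nodes, int me,
                       std::vector<int> &leaf_of) {
  const int n = idx.size(), p = X.ncol();
  nodes[me].n = n;
  bool stop_here = depth >= max_depth || n < 2 * min_leaf;
  int best_f = -1;
  double best_gain = 1e-12, best_thr = 0.0;
  if (!stop_here) {
    double tot = 0.0;
    for (int i : idx) tot += y[i];
    std::vector<std::pair<double, int> > ord(n);
    for (int f = 0; f < p; ++f) {
      for (int t = 0; t < n; ++t) ord[t] = std::make_pair(X(idx[t], f), idx[t]);
      std::sort(ord.begin(), ord.end());
      double sl = 0.0;
      for (int t = 0; t < n - 1; ++t) {
        sl += y[ord[t].second];
        if (ord[t].first == ord[t + 1].first) continue;  // no valid threshold
        int nl = t + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double sr = tot - sl;
        double gain = sl * sl / nl + sr * sr / nr - tot * tot / n;
        if (gain > best_gain) {  // strict ">" keeps lowest feature index on ties
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (ord[t].first + ord[t + 1].first);
        }
      }
    }
  }
  if (best_f < 0) {
    for (int i : idx) leaf_of[i] = me;
    return;
  }
  nodes[me].feature = best_f;
  nodes[me].threshold = best_thr;
  std::vector<int> li, ri;
  for (int i : idx) (X(i, best_f) <= best_thr ? li : ri).push_back(i);
  nodes.push_back(Node());
  int lc = nodes.size() - 1;
  nodes[me].left = lc;
  split_node(X, y, li, depth + 1, max_depth, min_leaf, nodes, lc, leaf_of);
  nodes.push_back(Node());
  int rc = nodes.size() - 1;
  nodes[me].right = rc;
  split_node(X, y, ri, depth + 1, max_depth, min_leaf, nodes, rc, leaf_of);
}

// [[Rcpp::export]]
List build_tree_cpp(NumericMatrix X, NumericVector y, int max_depth,
                    int min_leaf) {
  const int n = X.nrow();
  if (y.size() != n) stop("build_tree_cpp: length mismatch");
  std::vector<Node> nodes(1);
  std::vector<int> idx(n), leaf_of(n, 0);
  for (int i = 0; i < n; ++i) idx[i] = i;
  split_node(X, y, idx, 0, max_depth, min_leaf, nodes, 0, leaf_of);
  const int m = nodes.size();
  IntegerVector feature(m), left(m), right(m), nn(m), leaf(n);
  NumericVector thr(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    thr[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    nn[i] = nodes[i].n;
    value[i] = 0.0;
  }
  for (int i = 0; i < n; ++i) leaf[i] = leaf_of[i];
  return List::create(_["feature"] = feature, _["threshold"] = thr,
                      _["left"] = left, _["right"] = right, _["value"] = value,
                      _["n_node"] = nn, _["leaf"] = leaf);
}

static double tree_predict_row(const IntegerVector &feature,
                               const NumericVector &thr,
                               const IntegerVector &left,
                               const IntegerVector &right,
                               const NumericVector &value,
                               const NumericMatrix &X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = X(row, feature[node]) <= thr[node] ? left[node] : right[node];
  return value[node];
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector thr = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = tree_predict_row(feature, thr, left, right, value, X, i);
  return out;
}

// ---- exact interventional Shapley for a tree ensemble ----------------------
//
// For one explicand x, one background row r and one leaf with value V, the
// coalition game v(S) = f(hybrid: x on S, r off S) reaches the leaf iff every
// path feature whose constraints only x satisfies is in S and every path
// feature whose constraints only r satisfies is not in S. For that AND/NOT
// game the Shapley value has the closed form
//   phi_i = +V * (a-1)! b! / (a+b)!   for i among the a "x-only" features,
//   phi_i = -V * a! (b-1)! / (a+b)!   for i among the b "r-only" features,
// features satisfied by both (or off path) get zero. Summing over leaves,
// trees and background rows gives attributions with exact local accuracy:
// sum_i phi_i = f(x) - mean_r f(r).

struct LeafPath {
  double value;
  std::vector<int> feats;                  // distinct features on path
  std::vector<std::vector<double> > lo, hi;  // per feature: (lo, hi] intervals
};

static void collect_leaves(const IntegerVector &feature,
                           const NumericVector &thr, const IntegerVector &left,
                           const IntegerVector &right,
                           const NumericVector &value, int node,
                           std::vector<int> &pf, std::vector<double> &plo,
                           std::vector<double> &phi_,
                           std::vector<LeafPath> &out) {
  if (feature[node] < 0) {
    LeafPath lp;
    lp.value = value[node];
    for (size_t i = 0; i < pf.size(); ++i) {
      int f = pf[i];
      int pos = -1;
      for (size_t k = 0; k < lp.feats.size(); ++k)
        if (lp.feats[k] == f) pos = k;
      if (pos < 0) {
        lp.feats.push_back(f);
        lp.lo.push_back(std::vector<double>());
        lp.hi.push_back(std::vector<double>());
        pos = lp.feats.size() - 1;
      }
      lp.lo[pos].push_back(plo[i]);
      lp.hi[pos].push_back(phi_[i]);
    }
    out.push_back(lp);
    return;
  }
  // left branch: x[f] <= thr  -> interval (-inf, thr]
  pf.push_back(feature[node]);
  plo.push_back(R_NegInf);
  phi_.push_back(thr[node]);
  collect_leaves(feature, thr, left, right, value, left[node], pf, plo, phi_, out);
  plo.back() = thr[node];
  phi_.back() = R_PosInf;
  collect_leaves(feature, thr, left, right, value, right[node], pf, plo, phi_, out);
  pf.pop_back();
  plo.pop_back();
  phi_.pop_back();
}

static inline bool satisfies(double v, const std::vector<double> &lo,
                             const std::vector<double> &hi) {
  for (size_t c = 0; c < lo.size(); ++c)
    if (!(v > lo[c] && v <= hi[c])) return false;
  return true;
}

// trees: list of list(feature, threshold, left, right, value); X explicands
// (n x p); B background rows (nb x p). Returns n x p attribution matrix.
// [[Rcpp::export]]
NumericMatrix shap_trees_cpp(List trees, NumericMatrix X, NumericMatrix B) {
  const int n = X.nrow(), p = X.ncol(), nb = B.nrow();
  if (B.ncol() != p) stop("shap_trees_cpp: background column mismatch");
  if (nb == 0) stop("shap_trees_cpp: empty background");
  std::vector<double> fact(64);
  fact[0] = 1.0;
  for (int i = 1; i < 64; ++i) fact[i] = fact[i - 1] * i;
  NumericMatrix phi(n, p);

  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["threshold"], value = tr["value"];
    std::vector<LeafPath> leaves;
    {
      std::vector<int> pf;
      std::vector<double> plo, phi_;
      collect_leaves(feature, thr, left, right, value, 0, pf, plo, phi_, leaves);
    }
    const int nl = leaves.size();
    // precompute constraint satisfaction per leaf-feature for X and B rows
    std::vector<std::vector<std::vector<char> > > sx(nl), sb(nl);
    for (int l = 0; l < nl; ++l) {
      const LeafPath &lp = leaves[l];
      sx[l].resize(lp.feats.size());
      sb[l].resize(lp.feats.size());
      for (size_t d = 0; d < lp.feats.size(); ++d) {
        sx[l][d].resize(n);
        sb[l][d].resize(nb);
        const int f = lp.feats[d];
        for (int i = 0; i < n; ++i)
          sx[l][d][i] = satisfies(X(i, f), lp.lo[d], lp.hi[d]);
        for (int r = 0; r < nb; ++r)
          sb[l][d][r] = satisfies(B(r, f), lp.lo[d], lp.hi[d]);
      }
    }
    for (int i = 0; i < n; ++i) {
      for (int r = 0; r < nb; ++r) {
        for (int l = 0; l < nl; ++l) {
          const LeafPath &lp = leaves[l];
          const int nd = lp.feats.size();
          if (nd == 0) continue;  // root-leaf: no players
          int a = 0, b = 0;
          bool dead = false;
          // first pass: counts
          for (int d = 0; d < nd; ++d) {
            const bool cx = sx[l][d][i], cr = sb[l][d][r];
            if (cx && !cr) ++a;
            else if (!cx && cr) ++b;
            else if (!cx && !cr) { dead = true; break; }
          }
          if (dead || (a == 0 && b == 0)) continue;
          const double V = lp.value;
          const double wA = a > 0 ? V * fact[a - 1] * fact[b] / fact[a + b] : 0.0;
          const double wB = b > 0 ? V * fact[a] * fact[b - 1] / fact[a + b] : 0.0;
          for (int d = 0; d < nd; ++d) {
            const bool cx = sx[l][d][i], cr = sb[l][d][r];
            if (cx && !cr) phi(i, lp.feats[d]) += wA;
            else if (!cx && cr) phi(i, lp.feats[d]) -= wB;
          }
        }
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) phi(i, j) /= nb;
  return phi;
}
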