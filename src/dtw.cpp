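#include <Rcpp.h>
using namespace Rcpp;

// Classic unconstrained dynamic time warping with absolute-difference local
// cost. D(1,1) = |a1 - b1|; D(i,j) = |a_i - b_j| + min(D(i-1,j), D(i,j-1),
// D(i-1,j-1)). Two rolling rows keep memory at O(len(b)).
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b) {
  const int na = a.size(), nb = b.size();
  if (na == 0 || nb == 0) stop("dtw_cost_cpp: empty sequence");
  std::vector<double> prev(nb), cur(nb);
  prev[0] = std::abs(a[0] - b[0]);
  for (int j = 1; j < nb; ++j) prev[j] = prev[j - 1] + std::abs(a[0] - b[j]);
  for (int i = 1; i < na; ++i) {
    cur[0] = prev[0] + std::abs(a[i] - b[0]);
    for (int j = 1; j < nb; ++j) {
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = best + std::abs(a[i] - b[j]);
    }
    std::swap(prev, cur);
  }
  return prev[nb - 1];
}

// Pairwise patient distances: mean over lab variables of the univariate DTW
// cost between the two patients' series for that variable, optionally
// weighted. `series` is a list over patients; each element is a list over
// variables of numeric vectors (all nonempty after imputation).
// [[Rcpp::export]]
NumericMatrix dtw_distmat_cpp(List series, NumericVector weights) {
  const int n = series.size();
  if (n == 0) stop("dtw_distmat_cpp: no patients");
  const int nv = as<List>(series[0]).size();
  if (weights.size() != nv) stop("dtw_distmat_cpp: weight length mismatch");
  double wsum = 0.0;
  for (int v = 0; v < nv; ++v) wsum += weights[v];
  if (wsum <= 0) stop("dtw_distmat_cpp: weights must have positive sum");

  // materialize once to avoid repeated List coercion in the O(n^2) loop
  std::vector<std::vector<NumericVector> > S(n);
  for (int i = 0; i < n; ++i) {
    List li = series[i];
    if (li.size() != nv) stop("dtw_distmat_cpp: ragged variable lists");
    for (int v = 0; v < nv; ++v) {
      NumericVector sv = li[v];
      if (sv.size() == 0) stop("dtw_distmat_cpp: empty series (impute first)");
      S[i].push_back(sv);
    }
  }
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double acc = 0.0;
      for (int v = 0; v < nv; ++v)
        acc += weights[v] * dtw_cost_cpp(S[i][v], S[j][v]);
      double d = acc / wsum;
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
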