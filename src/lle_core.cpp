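// Locally linear embedding inner loops: exact p-nearest-neighbour search
// and the constrained reconstruction-weight solve. Kept in C++ because the
// pipeline runs thousands of ~1800-point trajectories.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exact p nearest neighbours by Euclidean distance, self excluded,
// ties broken toward the lower index. Returns an n x p 1-based index matrix
// with columns ordered by increasing distance.
// [[Rcpp::export(name = ".knn_cpp")]]
IntegerMatrix knn_cpp(const arma::mat& pts, int p) {
  const int n = pts.n_rows, d = pts.n_cols;
  const arma::mat P = pts.t();  // column i = point i, contiguous
  IntegerMatrix out(n, p);
  std::vector<std::pair<double, int>> cand(n - 1);
  for (int i = 0; i < n; ++i) {
    const double* pi = P.colptr(i);
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double* pj = P.colptr(j);
      double d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double dif = pi[k] - pj[k];
        d2 += dif * dif;
      }
      cand[m++] = std::make_pair(d2, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + p, cand.end());
    for (int k = 0; k < p; ++k) out(i, k) = cand[k].second + 1;
  }
  return out;
}

// Row-wise LLE reconstruction weights. For each point, solve the local Gram
// system G w = 1 over its neighbours, after adding reg * trace(G) / p to the
// diagonal (conditioning; required whenever p exceeds the input dimension),
// then normalise to sum 1. Returns an n x p weight matrix aligned with nb.
// [[Rcpp::export(name = ".lle_weights_cpp")]]
NumericMatrix lle_weights_cpp(const arma::mat& pts, const IntegerMatrix& nb,
                              double reg) {
  const int n = pts.n_rows, p = nb.ncol();
  NumericMatrix out(n, p);
  arma::mat G(p, pts.n_cols);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < p; ++k)
      G.row(k) = pts.row(nb(i, k) - 1) - pts.row(i);
    arma::mat Gm = G * G.t();
    double tr = arma::trace(Gm);
    if (tr <= 0.0) tr = 1.0;
    Gm.diag() += reg * tr / p;
    arma::vec w;
    if (!arma::solve(w, Gm, arma::ones<arma::vec>(p),
                     arma::solve_opts::no_approx)) {
      Gm.diag() += tr / p;  // fall back to a heavier ridge on breakdown
      w = arma::solve(Gm, arma::ones<arma::vec>(p));
    }
    w /= arma::accu(w);
    for (int k = 0; k < p; ++k) out(i, k) = w(k);
  }
  return out;
}
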