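// Numerical kernels: minimal-RMSD superposition (Kabsch, via singular values
// only -- the rotation itself is not needed for a distance matrix) and Markov
// mode-path sampling.  Uniform variates are drawn on the R side so that all
// randomness flows through R's RNG and set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double pair_rmsd_centered(const arma::mat& A, const arma::mat& B) {
  // A, B: n x 3, already centered on their centroids.  The optimal rotation
  // is built explicitly and the RMSD taken from the residuals: unlike the
  // singular-value shortcut this does not cancel catastrophically when the
  // two frames are near-identical.
  arma::mat H = A.t() * B;          // 3 x 3 covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t()) < 0.0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  arma::mat R = U * D * V.t();      // A * R best matches B
  double msd = arma::accu(arma::square(A * R - B)) /
    static_cast<double>(A.n_rows);
  return msd > 0.0 ? std::sqrt(msd) : 0.0;
}

// [[Rcpp::export]]
double cpp_pair_rmsd(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows != B.n_rows || A.n_cols != 3 || B.n_cols != 3)
    stop("coordinate sets must be n x 3 with matching atom counts");
  arma::mat Ac = A.each_row() - arma::mean(A, 0);
  arma::mat Bc = B.each_row() - arma::mean(B, 0);
  return pair_rmsd_centered(Ac, Bc);
}

// coords: cube n_atoms x 3 x n_frames; returns the full symmetric matrix of
// minimal superposed RMSDs between frames.
// [[Rcpp::export]]
arma::mat cpp_rmsd_matrix(const arma::cube& coords) {
  const arma::uword nf = coords.n_slices;
  std::vector<arma::mat> centered(nf);
  for (arma::uword i = 0; i < nf; ++i) {
    arma::mat M = coords.slice(i);
    centered[i] = M.each_row() - arma::mean(M, 0);
  }
  arma::mat D(nf, nf, arma::fill::zeros);
  for (arma::uword i = 0; i < nf; ++i) {
    for (arma::uword j = i + 1; j < nf; ++j) {
      double r = pair_rmsd_centered(centered[i], centered[j]);
      D(i, j) = r;
      D(j, i) = r;
    }
  }
  return D;
}

// P: k x k row-stochastic switching matrix; init: 1-based start mode;
// u: pre-drawn uniforms, one per step after the first.
// Returns 1-based mode indices of length u.n_elem + 1.
// [[Rcpp::export]]
IntegerVector cpp_markov_path(const arma::mat& P, int init, const arma::vec& u) {
  const int k = P.n_rows;
  const arma::uword n = u.n_elem + 1;
  IntegerVector path(n);
  int state = init - 1;
  path[0] = state + 1;
  for (arma::uword t = 1; t < n; ++t) {
    double x = u(t - 1), acc = 0.0;
    int next = k - 1;
    for (int j = 0; j < k; ++j) {
      acc += P(state, j);
      if (x <= acc) { next = j; break; }
    }
    state = next;
    path[t] = state + 1;
  }
  return path;
}
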