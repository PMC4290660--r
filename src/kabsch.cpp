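// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Optimal proper rotation superposing B onto A (both N x 3, same N).
// Reflection is prevented by flipping the sign of the singular vector
// associated with the smallest singular value when det < 0.
static void kabsch_core(const arma::mat& A, const arma::mat& B,
                        arma::mat& R, arma::rowvec& cenA, arma::rowvec& cenB,
                        double& rmsd_out) {
  cenA = arma::mean(A, 0);
  cenB = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - cenA;
  arma::mat Bc = B.each_row() - cenB;

  arma::mat H = Bc.t() * Ac;  // 3 x 3 covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);

  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  if (d < 0.0) D(2, 2) = -1.0;
  R = V * D * U.t();

  arma::mat Bfit = Bc * R.t();
  double msd = arma::accu(arma::square(Ac - Bfit)) / A.n_rows;
  rmsd_out = std::sqrt(std::max(msd, 0.0));
}

// [[Rcpp::export]]
List kabsch_cpp(const arma::mat& A, const arma::mat& B) {
  arma::mat R;
  arma::rowvec cenA, cenB;
  double r;
  kabsch_core(A, B, R, cenA, cenB, r);
  arma::vec t = cenA.t() - R * cenB.t();
  return List::create(_["rotation"] = R,
                      _["translation"] = t,
                      _["rmsd"] = r);
}

// [[Rcpp::export]]
double kabsch_rmsd_cpp(const arma::mat& A, const arma::mat& B) {
  arma::mat R;
  arma::rowvec cenA, cenB;
  double r;
  kabsch_core(A, B, R, cenA, cenB, r);
  return r;
}

// Superposed RMSD between every pair (x_i, y_j); xs and ys are lists of
// conformable N x 3 coordinate matrices. Used by the clustering stage.
// [[Rcpp::export]]
arma::mat rmsd_cross_cpp(const List& xs, const List& ys) {
  const int nx = xs.size(), ny = ys.size();
  arma::mat out(nx, ny);
  std::vector<arma::mat> ymats(ny);
  for (int j = 0; j < ny; ++j) ymats[j] = as<arma::mat>(ys[j]);
  arma::mat R;
  arma::rowvec cenA, cenB;
  double r;
  for (int i = 0; i < nx; ++i) {
    arma::mat x = as<arma::mat>(xs[i]);
    for (int j = 0; j < ny; ++j) {
      kabsch_core(x, ymats[j], R, cenA, cenB, r);
      out(i, j) = r;
    }
  }
  return out;
}

// Mean of members after least-squares fitting each onto `ref`
// (the centroid update of the clustering stage).
// [[Rcpp::export]]
arma::mat fit_mean_cpp(const List& xs, const arma::mat& ref) {
  const int n = xs.size();
  arma::mat acc(ref.n_rows, 3, arma::fill::zeros);
  arma::mat R;
  arma::rowvec cenA, cenB;
  double r;
  for (int i = 0; i < n; ++i) {
    arma::mat x = as<arma::mat>(xs[i]);
    kabsch_core(ref, x, R, cenA, cenB, r);
    arma::mat fit = (x.each_row() - cenB) * R.t();
    fit.each_row() += cenA;
    acc += fit;
  }
  return acc / n;
}
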