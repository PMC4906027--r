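#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-person pieces of the profiled Gaussian mixed-model deviance.
//
// The marginal covariance of person i, per unit residual variance, is
//   V*_i = I + Z_i Lambda Z_i' + s^2 D_i D_i'
// with Lambda = L L' the relative person-level covariance and D_i the
// day-intercept indicator matrix (columns orthogonal, D_i'D_i diagonal).
// Writing U = [Z L, s D], det(V*) = det(I_{q+Nd} + U'U) and
// V*^{-1} = I - U M^{-1} U' with M = I + U'U, so everything reduces to the
// precomputed cross-products Z'Z, Z'[X y], [X y]'[X y], day counts, and the
// day sums of [X y] and Z. M is inverted by block elimination on its
// diagonal day block (Schur complement on the small q x q corner).
//
// Returns sum_i log det V*_i and Cw = sum_i [X y]' V*_i^{-1} [X y], from
// which the caller profiles out the fixed effects and residual variance.
// [[Rcpp::export]]
List esmar_lik_parts(List prep, const arma::mat& L, double s, bool day) {
  const int np = prep.size();
  double ld = 0.0;
  arma::mat Cw;
  bool init = false;
  for (int i = 0; i < np; ++i) {
    List pp = prep[i];
    arma::mat Czz = pp["Czz"];
    arma::mat Czm = pp["Czm"];
    arma::mat Cmm = pp["Cmm"];
    const int m = Cmm.n_cols;
    const int q = Czz.n_cols;
    if (!init) { Cw = arma::zeros(m, m); init = true; }
    arma::mat A0 = L.t() * Czz * L;
    arma::mat u1 = L.t() * Czm;
    arma::mat Cvm;
    if (day) {
      arma::vec ndv = pp["ndv"];
      arma::mat Sdm = pp["Sdm"];
      arma::mat Sdz = pp["Sdz"];
      arma::vec cd = 1.0 + s * s * ndv;
      arma::mat B0 = s * (L.t() * Sdz.t());       // q x Nd
      arma::mat u2 = s * Sdm;                     // Nd x m
      arma::mat w2 = u2.each_col() / cd;
      arma::mat B0s = B0;
      B0s.each_row() /= cd.t();
      arma::mat E = arma::eye(q, q) + A0 - B0s * B0.t();
      arma::mat t1 = u1 - B0 * w2;
      arma::mat R = arma::chol(E, "lower");
      arma::mat tmp = arma::solve(arma::trimatl(R), t1);
      Cvm = Cmm - u2.t() * w2 - tmp.t() * tmp;
      ld += arma::accu(arma::log(cd)) + 2.0 * arma::accu(arma::log(R.diag()));
    } else {
      arma::mat M = arma::eye(q, q) + A0;
      arma::mat R = arma::chol(M, "lower");
      arma::mat tmp = arma::solve(arma::trimatl(R), u1);
      Cvm = Cmm - tmp.t() * tmp;
      ld += 2.0 * arma::accu(arma::log(R.diag()));
    }
    Cw += Cvm;
  }
  return List::create(_["ld"] = ld, _["Cw"] = Cw);
}
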