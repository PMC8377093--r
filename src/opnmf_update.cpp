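// Inner loop of orthonormal projective NMF.
//
// Minimizes ||X - W W' X||_F^2 over element-wise non-negative W (p x k) by
// the multiplicative update
//     W <- W * (A W) / (W (W' A W)),   A = X X'
// A is precomputed once per fit (p x p; p is the number of items, small).
// The objective is evaluated through A only:
//     ||X - W W' X||_F^2 = tr(A) - 2 tr(W' A W) + tr((W' A W)(W' W))
// so each iteration costs O(p^2 k), independent of the number of subjects.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".opnmf_update_cpp")]]
Rcpp::List opnmf_update_cpp(const arma::mat& A, const arma::mat& W0,
                            int max_iter, double tol, double eps_guard) {
  mat W = W0;
  const double trA = trace(A);

  std::vector<double> obj;
  obj.reserve(256);

  mat AW = A * W;
  mat WtAW = W.t() * AW;
  double f = trA - 2.0 * trace(WtAW) + trace(WtAW * (W.t() * W));
  obj.push_back(f);

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    mat denom = W * WtAW;
    W = W % (AW / (denom + eps_guard));
    // rescale to unit spectral norm each step: the multiplicative rule is
    // scale-sensitive and oscillates without it
    double nrm = norm(W, 2);
    if (nrm > 0) W /= nrm;

    AW = A * W;
    WtAW = W.t() * AW;
    double f_new = trA - 2.0 * trace(WtAW) + trace(WtAW * (W.t() * W));
    obj.push_back(f_new);

    double denom_f = std::abs(f) > 0 ? std::abs(f) : 1.0;
    if (std::abs(f - f_new) / denom_f < tol) {
      f = f_new;
      converged = true;
      break;
    }
    f = f_new;
  }

  return Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("objective_trace") = obj,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iter") = std::min(iter, max_iter));
}
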