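// Affine moving-least-squares deformation in 3D.
//
// For a query point v and control points p_i -> q_i with weights
// w_i = 1 / |p_i - v|^(2*alpha), the point-wise affine map minimizing
// sum_i w_i |A p_i + b - q_i|^2 is
//   f(v) = A (v - p*) + q*,  A = (sum w q^_i p^_i^T)(sum w p^_i p^_i^T)^{-1}
// with weighted centroids p*, q* and centered points p^, q^.  Queries closer
// than eps to a control point return the corresponding target exactly
// (diverging-weight limit).  If the weighted covariance is numerically
// singular (coplanar/collinear controls) the solve falls back to a weighted
// rigid (Kabsch) map and flags it.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_mls_apply(NumericMatrix V, NumericMatrix P, NumericMatrix Q,
                   double alpha, double eps, double cond_tol) {
  const int nq = V.nrow(), n = P.nrow();
  NumericMatrix out(nq, 3);
  bool any_fallback = false;
  arma::mat p(n, 3), q(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) { p(i, j) = P(i, j); q(i, j) = Q(i, j); }
  arma::vec w(n);
  for (int t = 0; t < nq; ++t) {
    const arma::rowvec v = { V(t, 0), V(t, 1), V(t, 2) };
    int exact = -1;
    for (int i = 0; i < n; ++i) {
      const double dx = p(i,0)-v[0], dy = p(i,1)-v[1], dz = p(i,2)-v[2];
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < eps * eps) { exact = i; break; }
      w[i] = 1.0 / std::pow(d2, alpha);
    }
    if (exact >= 0) {
      for (int j = 0; j < 3; ++j) out(t, j) = q(exact, j);
      continue;
    }
    const double wsum = arma::accu(w);
    const arma::rowvec pstar = (w.t() * p) / wsum;
    const arma::rowvec qstar = (w.t() * q) / wsum;
    arma::mat S(3, 3, arma::fill::zeros), C(3, 3, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      const arma::rowvec ph = p.row(i) - pstar;
      const arma::rowvec qh = q.row(i) - qstar;
      S += w[i] * (ph.t() * ph);
      C += w[i] * (qh.t() * ph);
    }
    arma::vec ev = arma::eig_sym(arma::symmatu(S));
    const bool ill = ev[0] < cond_tol * ev[2];  // near-coplanar controls
    arma::mat A;
    bool ok = !ill &&
      arma::solve(A, S.t(), C.t(), arma::solve_opts::no_approx);
    // A holds S^{-T} C^T = (C S^{-1})^T; f(v) = (v - p*) A + q*
    if (!ok || !A.is_finite()) {
      // weighted rigid fallback (Kabsch)
      any_fallback = true;
      arma::mat U, W;
      arma::vec s;
      arma::svd(U, s, W, C); // C = sum w qh^T ph
      arma::mat R = U * W.t();
      if (arma::det(R) < 0) { U.col(2) *= -1.0; R = U * W.t(); }
      A = R.t();
    }
    const arma::rowvec res = (v - pstar) * A + qstar;
    for (int j = 0; j < 3; ++j) out(t, j) = res[j];
  }
  return List::create(_["points"] = out, _["fallback"] = any_fallback);
}
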