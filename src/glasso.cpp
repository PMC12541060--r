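#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Graphical lasso by block coordinate descent (Friedman et al. style) with
// an elementwise penalty matrix. S must be a covariance/correlation matrix;
// the diagonal of Rho acts as a ridge on the estimated covariance diagonal.
// Returns the precision matrix Omega.
// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, const arma::mat& Rho,
                      int max_iter = 100, double tol = 1e-4,
                      int max_inner = 200, double inner_tol = 1e-6) {
  const uword p = S.n_rows;
  mat W = S;
  W.diag() += Rho.diag();
  mat B(p, p, fill::zeros);  // lasso coefficients per column
  double thr = tol * mean(mean(abs(S - diagmat(S.diag())))) ;
  if (thr <= 0) thr = tol * 1e-8;
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter && !converged; ++iter) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      // indices excluding j
      uvec idx(p - 1);
      uword c = 0;
      for (uword t = 0; t < p; ++t) if (t != j) idx(c++) = t;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec r12 = Rho.col(j); r12 = r12.elem(idx);
      vec beta = B.col(j); beta = beta.elem(idx);
      // coordinate descent for: min 0.5 b'W11 b - s12'b + sum r|b|
      vec grad = W11 * beta;
      for (int inner = 0; inner < max_inner; ++inner) {
        double delta = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double old = beta(k);
          double resid = s12(k) - (grad(k) - W11(k, k) * old);
          double bnew = soft(resid, r12(k)) / W11(k, k);
          if (bnew != old) {
            beta(k) = bnew;
            grad += W11.col(k) * (bnew - old);
            double d = std::abs(bnew - old);
            if (d > delta) delta = d;
          }
        }
        if (delta < inner_tol) break;
      }
      vec w12 = W11 * beta;
      double dmax = 0.0;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > dmax) dmax = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
      if (dmax > max_delta) max_delta = dmax;
      for (uword k = 0; k < p - 1; ++k) B(idx(k), j) = beta(k);
    }
    if (max_delta < thr) converged = true;
  }
  // recover precision matrix from W and B
  mat Omega(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword t = 0; t < p; ++t) if (t != j) idx(c++) = t;
    vec beta = B.col(j); beta = beta.elem(idx);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double theta_jj = 1.0 / (W(j, j) - dot(w12, beta));
    Omega(j, j) = theta_jj;
    for (uword k = 0; k < p - 1; ++k) {
      Omega(idx(k), j) = -beta(k) * theta_jj;
    }
  }
  Omega = 0.5 * (Omega + Omega.t());
  return Rcpp::List::create(Rcpp::Named("omega") = Omega,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = converged);
}
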