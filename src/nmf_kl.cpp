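#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// KL-divergence (Brunet) multiplicative updates with the connectivity
// stopping rule: stop once the argmax-H assignment has been stable for
// `stable_checks` consecutive checks (every 10 iterations).
// [[Rcpp::export(name = ".nmf_kl_cpp")]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter = 300, double tol = 1e-6,
                      int stable_checks = 4, double eps = 1e-10) {
  const uword n = V.n_rows, m = V.n_cols, k = W.n_cols;
  mat WH(n, m);
  uvec cluster(m, fill::zeros);
  int stable = 0, it = 0;
  double obj = datum::inf, obj_prev = datum::inf;
  for (it = 1; it <= max_iter; ++it) {
    WH = W * H + eps;
    H %= (W.t() * (V / WH));
    H.each_col() /= (sum(W, 0).t() + eps);
    WH = W * H + eps;
    W %= ((V / WH) * H.t());
    W.each_row() /= (sum(H, 1).t() + eps);
    if (it % 10 == 0 || it == max_iter) {
      uvec cl_new = index_max(H, 0).t();
      stable = (all(cl_new == cluster)) ? stable + 1 : 0;
      cluster = cl_new;
      WH = W * H + eps;
      obj = accu(V % log((V + eps) / WH) - V + WH);
      if (stable >= stable_checks) break;
      if (std::isfinite(obj_prev) &&
          std::abs(obj_prev - obj) < tol * std::abs(obj_prev)) break;
      obj_prev = obj;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("H") = H,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("cluster") = Rcpp::IntegerVector(cluster.begin(), cluster.end()),
    Rcpp::Named("iterations") = std::min(it, max_iter));
}
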