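#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update NMF (Lee & Seung, Frobenius loss).
// X ~ W H, W: n x k, H: k x m, all non-negative. Initial factors are
// supplied from R so seeding stays under R's RNG. Returns the factors,
// the per-iteration objective trace, and a convergence flag.
// [[Rcpp::export(name = ".nmf_mu")]]
Rcpp::List nmf_mu(const arma::mat& X, arma::mat W, arma::mat H,
                  int max_iter, double tol) {
  const double eps = 1e-12;
  std::vector<double> trace;
  trace.reserve(max_iter);
  double prev = datum::inf;
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    // H <- H .* (W'X) ./ (W'W H)
    H %= (W.t() * X) / (W.t() * W * H + eps);
    // W <- W .* (X H') ./ (W H H')
    W %= (X * H.t()) / (W * (H * H.t()) + eps);
    double err = norm(X - W * H, "fro");
    trace.push_back(err);
    if (std::isfinite(prev) && std::abs(prev - err) <= tol * std::max(1.0, prev)) {
      converged = true;
      break;
    }
    prev = err;
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("error") = trace.empty() ? norm(X - W * H, "fro")
                                         : trace.back(),
    Rcpp::Named("trace") = trace,
    Rcpp::Named("converged") = converged);
}
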