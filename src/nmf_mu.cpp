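// Multiplicative-update NMF (squared Euclidean objective).
// The factor updates run in C++ because model selection refits the
// factorization hundreds of times (candidate ranks x cross-validation
// repetitions x restarts) on 12 x 1800-3000 matrices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One full factorization from the supplied initial factors.
// fix_w = true freezes W and iterates C only (held-out refit).
// Returns W, C, the Frobenius residual per iteration, and the
// iteration count at termination.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& M, arma::mat W, arma::mat C,
                      int max_iter, double tol, bool fix_w, double eps) {
  std::vector<double> resid;
  resid.reserve(max_iter + 1);
  double prev = norm(M - W * C, "fro");
  resid.push_back(prev);
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    if (!fix_w) {
      // W <- W .* (M C') ./ (W C C' + eps)
      mat num = M * C.t();
      mat den = W * (C * C.t());
      W %= num / (den + eps);
    }
    // C <- C .* (W' M) ./ (W' W C + eps)
    mat numc = W.t() * M;
    mat denc = (W.t() * W) * C;
    C %= numc / (denc + eps);

    double r = norm(M - W * C, "fro");
    resid.push_back(r);
    if (prev > 0 && std::abs(prev - r) / prev < tol) break;
    prev = r;
  }
  if (it > max_iter) it = max_iter;
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("C") = C,
                            Rcpp::Named("residuals") = resid,
                            Rcpp::Named("iterations") = it);
}
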