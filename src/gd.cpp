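#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Full-batch gradient descent for the affine sort-seq regression:
// minimize sum_i ||W x_i + b - y_i||^2 + lambda * ||W||_F^2
// from W = 0, b = 0 (the bias is unpenalized). Deterministic.
// [[Rcpp::export(name = ".affine_gd")]]
List affine_gd(const arma::mat& X, const arma::mat& Y, double lambda,
               double lr, int max_iters, double tol) {
  const arma::uword K = X.n_cols, B = Y.n_cols;
  arma::mat W(B, K, arma::fill::zeros);
  arma::vec b(B, arma::fill::zeros);
  arma::rowvec bt(B, arma::fill::zeros);

  double prev = arma::accu(arma::square(Y));  // loss at the zero model
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iters; ++it) {
    arma::mat R = X * W.t();
    R.each_row() += bt;
    R -= Y;
    arma::mat gW = 2.0 * (R.t() * X) + 2.0 * lambda * W;
    arma::rowvec gb = 2.0 * arma::sum(R, 0);
    W -= lr * gW;
    bt -= lr * gb;

    arma::mat R2 = X * W.t();
    R2.each_row() += bt;
    R2 -= Y;
    double loss = arma::accu(arma::square(R2)) +
      lambda * arma::accu(arma::square(W));
    if (!std::isfinite(loss) || loss > prev * 1.5 + 1e-12) {
      stop("gradient descent diverged (iteration %d); reduce the learning rate",
           it);
    }
    if (prev - loss < tol) {
      prev = loss;
      converged = true;
      break;
    }
    prev = loss;
  }
  b = bt.t();
  return List::create(_["W"] = W, _["b"] = b, _["final_loss"] = prev,
                      _["iterations"] = std::min(it, max_iters),
                      _["converged"] = converged);
}
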