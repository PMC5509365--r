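// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Batched projected gradient ascent on the Poisson log-likelihood:
//   X <- max(X + eta * W' * (S / (W X + w0) - 1), 0)
// columns are independent stimuli; converged columns (max per-step change
// below tol, checked every check_every iterations) are dropped from the
// working set.
// [[Rcpp::export]]
List divisive_dynamics_cpp(const arma::mat& W, double w0,
                           const arma::mat& S, const arma::mat& X0,
                           double eta, double tol, int max_iter,
                           int check_every) {
  const arma::uword n = W.n_cols, N = S.n_cols;
  arma::mat X = X0;                     // n x N, final answers
  arma::uvec active = arma::regspace<arma::uvec>(0, N - 1);
  arma::mat Xa = X.cols(active);
  arma::mat Sa = S.cols(active);
  arma::ivec iters(N, arma::fill::zeros);
  arma::uvec conv(N, arma::fill::ones);
  int it = 0;
  arma::mat lam, G, Xn;
  while (active.n_elem > 0 && it < max_iter) {
    ++it;
    lam = W * Xa;
    lam += w0;
    G = Sa / lam;
    G -= 1.0;
    Xn = Xa + eta * (W.t() * G);
    Xn.clamp(0.0, arma::datum::inf);
    if (it % check_every == 0 || it == max_iter) {
      arma::rowvec d = arma::max(arma::abs(Xn - Xa), 0);
      Xa = Xn;
      arma::uvec done = arma::find(d < tol);
      if (done.n_elem > 0) {
        for (arma::uword q = 0; q < done.n_elem; ++q) {
          arma::uword col = active(done(q));
          X.col(col) = Xa.col(done(q));
          iters(col) = it;
        }
        arma::uvec keep = arma::find(d >= tol);
        active = active(keep);
        Xa = Xa.cols(keep);
        Sa = Sa.cols(keep);
      }
    } else {
      Xa = Xn;
    }
  }
  for (arma::uword q = 0; q < active.n_elem; ++q) {
    X.col(active(q)) = Xa.col(q);
    iters(active(q)) = max_iter;
    conv(active(q)) = 0;
  }
  return List::create(_["X"] = X, _["iterations"] = iters,
                      _["converged"] = conv);
}
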