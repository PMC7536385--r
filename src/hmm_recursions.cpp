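// Scaled forward-backward and Viterbi recursions for a Gaussian-emission HMM.
// Emission log-densities are computed in R (vectorised Cholesky forms); only
// the serial time recursions live here. Per-timepoint max-shift plus
// normalisation keeps everything in a safe numeric range; the log-likelihood
// is recovered exactly from the scaling constants.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// logB: T x K log emission densities; pi: K initial probs; A: K x K transitions.
// Returns gamma (T x K posteriors), xi (K x K expected transition counts summed
// over t), gamma1 (posterior at t = 1), loglik.
// [[Rcpp::export(name = ".cpp_forward_backward")]]
List cpp_forward_backward(const arma::mat& logB, const arma::vec& pi,
                          const arma::mat& A) {
  const arma::uword T = logB.n_rows, K = logB.n_cols;
  arma::mat B(T, K), alpha(T, K), beta(T, K);
  arma::vec c(T), m(T);
  for (arma::uword t = 0; t < T; ++t) {
    m(t) = logB.row(t).max();
    if (!std::isfinite(m(t)))
      stop("all emission densities underflowed at timepoint %d; consider a larger covariance ridge", (int)(t + 1));
    B.row(t) = arma::exp(logB.row(t) - m(t));
  }
  double loglik = 0.0;
  alpha.row(0) = pi.t() % B.row(0);
  c(0) = arma::accu(alpha.row(0));
  if (c(0) <= 0.0)
    stop("zero total likelihood at timepoint 1; consider a larger covariance ridge");
  alpha.row(0) /= c(0);
  loglik += std::log(c(0)) + m(0);
  for (arma::uword t = 1; t < T; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * A) % B.row(t);
    c(t) = arma::accu(alpha.row(t));
    if (c(t) <= 0.0)
      stop("zero total likelihood at timepoint %d; consider a larger covariance ridge", (int)(t + 1));
    alpha.row(t) /= c(t);
    loglik += std::log(c(t)) + m(t);
  }
  beta.row(T - 1).ones();
  for (arma::uword t = T - 1; t-- > 0;) {
    beta.row(t) = ((B.row(t + 1) % beta.row(t + 1)) * A.t()) / c(t + 1);
  }
  arma::mat gamma = alpha % beta;
  for (arma::uword t = 0; t < T; ++t) gamma.row(t) /= arma::accu(gamma.row(t));
  arma::mat xi(K, K, arma::fill::zeros);
  for (arma::uword t = 0; t + 1 < T; ++t) {
    arma::mat xt = (alpha.row(t).t() * (B.row(t + 1) % beta.row(t + 1))) % A / c(t + 1);
    xi += xt;
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["gamma1"] = gamma.row(0).t(), _["loglik"] = loglik);
}

// Most probable state path; ties broken toward the lowest state index, both
// in the forward maximisation and at the terminal argmax.
// [[Rcpp::export(name = ".cpp_viterbi")]]
IntegerVector cpp_viterbi(const arma::mat& logB, const arma::vec& logpi,
                          const arma::mat& logA) {
  const arma::uword T = logB.n_rows, K = logB.n_cols;
  arma::mat delta(T, K);
  arma::umat psi(T, K, arma::fill::zeros);
  delta.row(0) = logpi.t() + logB.row(0);
  for (arma::uword t = 1; t < T; ++t) {
    for (arma::uword j = 0; j < K; ++j) {
      double best = -arma::datum::inf;
      arma::uword arg = 0;
      for (arma::uword i = 0; i < K; ++i) {
        double cand = delta(t - 1, i) + logA(i, j);
        if (cand > best) { best = cand; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = -arma::datum::inf;
  arma::uword arg = 0;
  for (arma::uword k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = (int)arg + 1;
  for (arma::uword t = T - 1; t-- > 0;) {
    arg = psi(t + 1, arg);
    path[t] = (int)arg + 1;
  }
  return path;
}
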