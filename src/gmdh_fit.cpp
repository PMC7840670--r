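#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fit all candidate two-input polynomial neurons of one GMDH layer.
//
// Z: n x m layer-input matrix; y: n targets; pairs: K x 2 matrix of 1-based
// column indexes (i1 != i2); fit_idx: 1-based rows of the fit subset A;
// eval_idx: 1-based rows on which the external error delta is measured.
// Each candidate solves the least-squares problem for the design
// [1, z1, z2, z1*z2] (the interaction column is dropped when
// interaction = false) on the A rows via the Cholesky-factored normal
// equations; candidates whose Gram matrix is not positive definite
// (collinear inputs) are marked unfit with delta = Inf.
//
// Returns coef (p x K), delta (K, Euclidean norm of the eval-row
// residuals), and yhat_eval (|eval_idx| x K, candidate outputs on the
// eval rows, used for correlation pruning). Outputs on all rows are only
// needed for the few selected neurons and are recomputed by the caller.
// [[Rcpp::export]]
List gmdh_fit_layer(const arma::mat& Z, const arma::vec& y,
                    const arma::imat& pairs, const arma::uvec& fit_idx,
                    const arma::uvec& eval_idx, const bool interaction) {
  const arma::uword K = pairs.n_rows;
  const arma::uword p = interaction ? 4 : 3;

  const arma::uvec fi = fit_idx - 1;
  const arma::uvec ei = eval_idx - 1;
  const arma::mat Zf = Z.rows(fi);
  const arma::mat Ze = Z.rows(ei);
  const arma::vec yf = y(fi);
  const arma::vec ye = y(ei);
  const arma::uword nf = Zf.n_rows, ne = Ze.n_rows;

  arma::mat coef(p, K, arma::fill::zeros);
  arma::vec delta(K, arma::fill::value(arma::datum::inf));
  arma::mat yhat_eval(ne, K, arma::fill::zeros);

  arma::mat Df(nf, p), De(ne, p);
  Df.col(0).ones();
  De.col(0).ones();
  arma::mat G(p, p), R(p, p);
  arma::vec w(p);

  for (arma::uword k = 0; k < K; ++k) {
    const arma::uword i1 = pairs(k, 0) - 1;
    const arma::uword i2 = pairs(k, 1) - 1;
    Df.col(1) = Zf.col(i1);
    Df.col(2) = Zf.col(i2);
    if (interaction) Df.col(3) = Zf.col(i1) % Zf.col(i2);

    G = Df.t() * Df;
    // guard against near-singular but still Cholesky-factorable designs
    if (!arma::chol(R, G) ||
        R.diag().min() < 1e-7 * (1.0 + R.diag().max())) continue;
    w = arma::solve(arma::trimatu(R),
                    arma::solve(arma::trimatl(R.t()), Df.t() * yf));

    De.col(1) = Ze.col(i1);
    De.col(2) = Ze.col(i2);
    if (interaction) De.col(3) = Ze.col(i1) % Ze.col(i2);
    const arma::vec pe = De * w;

    coef.col(k) = w;
    yhat_eval.col(k) = pe;
    delta(k) = arma::norm(pe - ye, 2);
  }

  return List::create(_["coef"] = coef, _["delta"] = delta,
                      _["yhat_eval"] = yhat_eval);
}
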