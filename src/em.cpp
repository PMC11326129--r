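// E-step of the template-ICA EM algorithm.
//
// Model at each vertex v: y_v = A s_v + e, e ~ N(0, nv I_Tp),
// s_v ~ N(m_v, diag(p_v)). Returns the per-vertex posterior mean and
// variance, the moment accumulators needed by the M-step, and the
// observed-data log-likelihood under the *current* (A, nv).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List em_estep(const arma::mat& Y,          // Tp x V
                    const arma::mat& A,          // Tp x Q
                    const double noise_var,
                    const arma::mat& prior_mean, // V x Q
                    const arma::mat& prior_var)  // V x Q
{
  const arma::uword Tp = Y.n_rows, V = Y.n_cols, Q = A.n_cols;
  const arma::mat AtA = A.t() * A;
  const double log2pi = std::log(2.0 * M_PI);

  arma::mat post_mean(V, Q), post_var(V, Q);
  arma::mat S1(Tp, Q, arma::fill::zeros);   // sum_v y_v E[s_v]'
  arma::mat S2(Q, Q, arma::fill::zeros);    // sum_v E[s_v s_v']
  double sum_y2 = 0.0, loglik = 0.0;

  for (arma::uword v = 0; v < V; ++v) {
    const arma::vec yv = Y.col(v);
    const arma::vec mv = prior_mean.row(v).t();
    const arma::vec pv = prior_var.row(v).t();

    // posterior precision and covariance
    arma::mat P = AtA / noise_var;
    P.diag() += 1.0 / pv;
    const arma::mat C = arma::inv_sympd(P);
    const arma::vec mu = C * (mv / pv + A.t() * yv / noise_var);

    post_mean.row(v) = mu.t();
    post_var.row(v) = C.diag().t();
    S1 += yv * mu.t();
    S2 += C + mu * mu.t();
    sum_y2 += arma::dot(yv, yv);

    // observed-data likelihood: y_v ~ N(A mv, A diag(pv) A' + nv I)
    arma::mat Sig = A * arma::diagmat(pv) * A.t();
    Sig.diag() += noise_var;
    const arma::vec r = yv - A * mv;
    double ldet, sign;
    arma::log_det(ldet, sign, Sig);
    loglik += -0.5 * (Tp * log2pi + ldet +
                      arma::dot(r, arma::solve(Sig, r, arma::solve_opts::likely_sympd)));
  }

  return Rcpp::List::create(
    Rcpp::Named("post_mean") = post_mean,
    Rcpp::Named("post_var") = post_var,
    Rcpp::Named("S1") = S1,
    Rcpp::Named("S2") = S2,
    Rcpp::Named("sum_y2") = sum_y2,
    Rcpp::Named("loglik") = loglik);
}
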