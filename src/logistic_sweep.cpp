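// Per-SNP logistic regression sweep.
//
// Fits, for each SNP, the maximum-likelihood logistic model
//   logit P(y = 1) = b0 + b_dosage * g_j + covariates
// by iteratively reweighted least squares. The design differs between SNPs
// only in the dosage column, so the sweep shares the base design and loops
// in native code; results agree with stats::glm to near machine precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".logistic_sweep")]]
Rcpp::List logistic_sweep(const arma::mat& base_X, const arma::mat& dosages,
                          const arma::vec& y, int maxit = 40,
                          double tol = 1e-9) {
  const uword n = base_X.n_rows;
  const uword p = base_X.n_cols + 1;  // + dosage column
  const uword J = dosages.n_cols;

  mat X(n, p);
  X.col(0).ones();
  if (base_X.n_cols > 1) {
    X.cols(2, p - 1) = base_X.cols(1, base_X.n_cols - 1);
  }

  vec beta_out(J, fill::value(datum::nan));
  vec se_out(J, fill::value(datum::nan));
  uvec converged(J, fill::zeros);

  for (uword j = 0; j < J; ++j) {
    X.col(1) = dosages.col(j);
    if (var(X.col(1)) < 1e-12) continue;  // degenerate column

    vec beta(p, fill::zeros);
    bool ok = false;
    for (int it = 0; it < maxit; ++it) {
      vec eta = X * beta;
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec w = mu % (1.0 - mu);
      w = clamp(w, 1e-10, 0.25);
      vec z = eta + (y - mu) / w;
      mat Xw = X.each_col() % w;
      mat XtWX = X.t() * Xw;
      vec XtWz = Xw.t() * z;
      vec beta_new;
      bool solved = solve(beta_new, XtWX, XtWz, solve_opts::no_approx);
      if (!solved || !beta_new.is_finite()) { ok = false; break; }
      double step = norm(beta_new - beta, "inf");
      beta = beta_new;
      if (step < tol * (norm(beta, "inf") + 0.1)) {
        ok = true;
        break;
      }
    }
    if (!ok) continue;

    vec eta = X * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
    mat XtWX = X.t() * (X.each_col() % w);
    mat cov;
    if (!inv_sympd(cov, XtWX)) continue;
    beta_out(j) = beta(1);
    se_out(j) = std::sqrt(cov(1, 1));
    converged(j) = 1;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta_out,
                            Rcpp::Named("se") = se_out,
                            Rcpp::Named("converged") = converged);
}
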