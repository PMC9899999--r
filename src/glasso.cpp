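#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Coordinate descent for the lasso subproblem
//   min_b 0.5 * b' V b - u' b + lambda * ||b||_1
// V is (p-1)x(p-1) PD, updated in place on b.
static void lasso_cd(const arma::mat& V, const arma::vec& u, arma::vec& b,
                     double lambda, int max_iter, double tol) {
  const arma::uword p = u.n_elem;
  for (int it = 0; it < max_iter; ++it) {
    double dmax = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      double bj_old = b(j);
      // partial residual: u_j - sum_{k != j} V_jk b_k
      double r = u(j) - arma::dot(V.col(j), b) + V(j, j) * bj_old;
      double bj = 0.0;
      if (r > lambda)       bj = (r - lambda) / V(j, j);
      else if (r < -lambda) bj = (r + lambda) / V(j, j);
      b(j) = bj;
      double d = std::abs(bj - bj_old);
      if (d > dmax) dmax = d;
    }
    if (dmax < tol) break;
  }
}

// Block coordinate descent graphical lasso (Friedman et al. style):
// estimate Theta maximising  log det(Theta) - tr(S Theta) - lambda * ||Theta||_1
// via its dual on the covariance estimate W = S + lambda*I (diagonal fixed).
// Supports warm starts in W/B for sliding-window sequences.
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda, int max_iter,
                      double tol,
                      Rcpp::Nullable<Rcpp::NumericMatrix> w_init = R_NilValue,
                      Rcpp::Nullable<Rcpp::NumericMatrix> b_init = R_NilValue) {
  const arma::uword p = S.n_rows;
  if (p == 1) {
    arma::mat W(1, 1); W(0, 0) = S(0, 0) + lambda;
    arma::mat Theta(1, 1); Theta(0, 0) = 1.0 / W(0, 0);
    return Rcpp::List::create(Rcpp::Named("w") = W, Rcpp::Named("theta") = Theta,
                              Rcpp::Named("beta") = arma::mat(1, 1, arma::fill::zeros),
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true);
  }

  arma::mat W;
  if (w_init.isNotNull()) {
    W = Rcpp::as<arma::mat>(w_init.get());
    W.diag() = S.diag() + lambda;  // diagonal is fixed by the KKT conditions
  } else {
    W = S;
    W.diag() += lambda;
  }
  arma::mat B(p, p, arma::fill::zeros);  // column j holds beta for block j
  if (b_init.isNotNull()) B = Rcpp::as<arma::mat>(b_init.get());

  // convergence threshold on mean absolute off-diagonal change, scaled to S
  double s_off = 0.0;
  for (arma::uword i = 0; i < p; ++i)
    for (arma::uword j = 0; j < p; ++j)
      if (i != j) s_off += std::abs(S(i, j));
  s_off /= (double)(p * (p - 1));
  const double thr = tol * std::max(s_off, 1e-12);

  int it = 0;
  bool converged = false;
  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);
  for (it = 1; it <= max_iter; ++it) {
    double dsum = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      arma::uvec idx = arma::find(all != j);
      arma::mat V = W(idx, idx);
      arma::vec u = S.col(j);
      u = u(idx);
      arma::vec b = B.col(j);
      b = b(idx);
      lasso_cd(V, u, b, lambda, 200, thr * 0.1);
      arma::vec w12 = V * b;
      for (arma::uword k = 0; k < idx.n_elem; ++k) {
        dsum += std::abs(W(idx(k), j) - w12(k));
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = b(k);
      }
    }
    if (dsum / (double)(p * (p - 1)) < thr) { converged = true; break; }
  }

  // recover the precision matrix from W and the block solutions
  arma::mat Theta(p, p, arma::fill::zeros);
  for (arma::uword j = 0; j < p; ++j) {
    arma::uvec idx = arma::find(all != j);
    arma::vec b = B.col(j);
    b = b(idx);
    arma::vec w12 = W.col(j);
    w12 = w12(idx);
    double t22 = 1.0 / (W(j, j) - arma::dot(w12, b));
    Theta(j, j) = t22;
    for (arma::uword k = 0; k < idx.n_elem; ++k) {
      double v = -b(k) * t22;
      Theta(idx(k), j) = v;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("w") = W, Rcpp::Named("theta") = Theta,
                            Rcpp::Named("beta") = B,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged);
}
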