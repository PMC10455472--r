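#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Graphical lasso by block coordinate descent on the covariance estimate W.
// For each column j the subproblem
//   min_beta 0.5 beta' W11 beta - s12' beta + rho ||beta||_1
// is solved by cyclic coordinate descent; w12 = W11 beta updates W.
// The diagonal is not penalized (w_jj = s_jj throughout), matching the
// convention of regularized partial-correlation networks in psychometrics.
//
// Warm starts: W and B persist across the (decreasing) lambda path.

static double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One full lasso solve for column j. B(.,j) holds beta (entry j unused).
// Residuals r_k = s12_k - sum_{m != j} W(k,m) beta_m are maintained
// incrementally, so each sweep costs O(p^2).
static int lasso_column(const mat& S, mat& W, mat& B, uword j, double rho,
                        double inner_tol, int inner_max) {
  const uword p = S.n_rows;
  vec r(p);
  for (uword k = 0; k < p; ++k) {
    double acc = S(k, j);
    for (uword m = 0; m < p; ++m)
      if (m != j) acc -= W(k, m) * B(m, j);
    r(k) = acc;
  }
  int it = 0;
  for (; it < inner_max; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      double g = r(k) + W(k, k) * B(k, j);  // gradient excluding coord k
      double bnew = soft_threshold(g, rho) / W(k, k);
      double d = bnew - B(k, j);
      if (d != 0.0) {
        B(k, j) = bnew;
        for (uword i = 0; i < p; ++i) r(i) -= W(i, k) * d;
        d = std::abs(d);
        if (d > dmax) dmax = d;
      }
    }
    if (dmax < inner_tol) break;
  }
  // w12 = W11 beta = s12 - r (up to the excluded column j)
  for (uword i = 0; i < p; ++i) {
    if (i == j) continue;
    double w = 0.0;
    for (uword m = 0; m < p; ++m)
      if (m != j) w += W(i, m) * B(m, j);
    W(i, j) = w;
    W(j, i) = w;
  }
  return it + 1;
}

// Recover the precision matrix Theta from (W, B).
static mat recover_theta(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double q = W(j, j);
    for (uword m = 0; m < p; ++m) {
      if (m == j) continue;
      q -= W(m, j) * B(m, j);
    }
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (uword m = 0; m < p; ++m) {
      if (m == j) continue;
      Theta(m, j) = -B(m, j) * tjj;
    }
  }
  // KKT conditions make the support symmetric at convergence; enforce both
  // exact-zero symmetry and numerical symmetry.
  mat Sym = 0.5 * (Theta + Theta.t());
  for (uword j = 0; j < p; ++j)
    for (uword m = j + 1; m < p; ++m)
      if (B(m, j) == 0.0 && B(j, m) == 0.0) {
        Sym(m, j) = 0.0;
        Sym(j, m) = 0.0;
      }
  return Sym;
}

// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol, int max_iter) {
  const uword p = S.n_rows;
  const uword nl = lambdas.n_elem;

  mat W = S;                  // unpenalized diagonal: W starts (and stays) at S on diag
  mat B(p, p, fill::zeros);

  // average absolute off-diagonal of S sets the convergence scale
  double offsum = 0.0;
  for (uword j = 0; j < p; ++j)
    for (uword i = 0; i < p; ++i)
      if (i != j) offsum += std::abs(S(i, j));
  double offmean = (p > 1) ? offsum / (double)(p * (p - 1)) : 1.0;
  double thr = tol * (offmean > 0 ? offmean : 1.0);
  double inner_tol = thr / 10.0;

  Rcpp::List thetas(nl);
  Rcpp::IntegerVector iters(nl);
  Rcpp::LogicalVector converged(nl);

  for (uword l = 0; l < nl; ++l) {
    double rho = lambdas(l);
    bool conv = false;
    int it = 0;
    for (; it < max_iter; ++it) {
      mat Wold = W;
      for (uword j = 0; j < p; ++j)
        lasso_column(S, W, B, j, rho, inner_tol, max_iter);
      double dmean = 0.0;
      for (uword j = 0; j < p; ++j)
        for (uword i = 0; i < p; ++i)
          if (i != j) dmean += std::abs(W(i, j) - Wold(i, j));
      dmean /= (double)(p * (p - 1));
      if (dmean < thr) { conv = true; ++it; break; }
    }
    thetas[l] = Rcpp::wrap(recover_theta(W, B));
    iters[l] = it;
    converged[l] = conv;
  }

  return Rcpp::List::create(Rcpp::Named("theta") = thetas,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("converged") = converged);
}
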