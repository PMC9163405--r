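#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Coordinate descent for the column subproblem
//   min_b 0.5 b' V b - b' u + rho ||b||_1
// warm-started at `b`.
static vec lasso_cd(const mat& V, const vec& u, double rho, vec b,
                    int max_iter, double tol) {
  const int p = u.n_elem;
  for (int it = 0; it < max_iter; ++it) {
    double dmax = 0.0;
    for (int j = 0; j < p; ++j) {
      double bj_old = b(j);
      // partial residual gradient excluding coordinate j
      double g = u(j) - dot(V.col(j), b) + V(j, j) * bj_old;
      double bj = 0.0;
      if (g > rho)       bj = (g - rho) / V(j, j);
      else if (g < -rho) bj = (g + rho) / V(j, j);
      b(j) = bj;
      double d = std::fabs(bj - bj_old);
      if (d > dmax) dmax = d;
    }
    if (dmax < tol) break;
  }
  return b;
}

// Graphical LASSO by block coordinate descent (Friedman et al. style).
// S must be symmetric with positive diagonal. Returns the regularized
// covariance W, the precision Theta, the duality gap and iteration count.
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho, int max_iter,
                      double tol) {
  const int p = S.n_rows;
  mat W = S;
  mat Theta(p, p, fill::zeros);
  bool converged = false;
  int iters = 0;

  if (rho <= 0.0) {
    Theta = inv_sympd(symmatu(S));
    W = S;
    converged = true;
  } else {
    W.diag() += rho;
    mat B(p - 1, p, fill::zeros);
    // convergence threshold on the average absolute change of W,
    // relative to the average absolute off-diagonal of S
    double off_mean = 0.0;
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (i != j) off_mean += std::fabs(S(i, j));
    off_mean /= std::max(1, p * (p - 1));
    double thr = tol * std::max(off_mean, 1e-12);

    uvec all = regspace<uvec>(0, p - 1);
    for (iters = 1; iters <= max_iter; ++iters) {
      double dmax = 0.0;
      for (int j = 0; j < p; ++j) {
        uvec idx = find(all != (unsigned) j);
        mat V = W(idx, idx);
        vec u = S.col(j);
        vec s12 = u(idx);
        vec b = lasso_cd(V, s12, rho, B.col(j), 200, 1e-8);
        B.col(j) = b;
        vec w12 = V * b;
        for (int i = 0; i < p - 1; ++i) {
          double d = std::fabs(W(idx(i), j) - w12(i));
          if (d > dmax) dmax = d;
          W(idx(i), j) = w12(i);
          W(j, idx(i)) = w12(i);
        }
      }
      if (dmax < thr) { converged = true; break; }
    }
    // recover Theta from W and the final regression coefficients
    for (int j = 0; j < p; ++j) {
      uvec idx = find(all != (unsigned) j);
      vec b = B.col(j);
      vec w12 = W.submat(idx, uvec{(unsigned) j});
      double t22 = 1.0 / (W(j, j) - dot(w12, b));
      Theta(j, j) = t22;
      for (int i = 0; i < p - 1; ++i) Theta(idx(i), j) = -b(i) * t22;
    }
    Theta = 0.5 * (Theta + Theta.t());
  }

  // duality gap for the diagonal-penalized problem solved here:
  // tr(S Theta) - p + rho * ||Theta||_1
  double gap = trace(S * Theta) - p + rho * accu(abs(Theta));

  return Rcpp::List::create(
      Rcpp::Named("w") = W,
      Rcpp::Named("theta") = Theta,
      Rcpp::Named("gap") = gap,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = iters);
}
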