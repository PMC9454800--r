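#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for the Lasso on the centered Gram system,
// warm-started along a decreasing penalty path.
//
// Solves, for each alpha, min_w (1/(2n)) ||y_c - X_c w||^2 + alpha ||w||_1
// given G = X_c'X_c / n and b = X_c'y_c / n (X_c, y_c mean-centered, so the
// intercept is handled outside).  Convergence: the largest scaled coefficient
// change |dw_j| * sqrt(G_jj) in a sweep falls below `tol`.
//
// Uses the standard active-set strategy: iterate over the nonzero set until
// converged, then one full sweep; if the full sweep changes the active set
// (or fails the tolerance) repeat, otherwise move to the next alpha.
//
// Columns with G_jj == 0 (constant in the training rows) get coefficient 0.
//
// [[Rcpp::export]]
NumericMatrix cd_lasso_path(NumericMatrix G, NumericVector b,
                            NumericVector alphas, double tol, int maxit) {
  const int p = b.size();
  const int na = alphas.size();
  if (G.nrow() != p || G.ncol() != p)
    stop("Gram matrix does not match gradient vector length");
  NumericMatrix beta(p, na);
  std::vector<double> w(p, 0.0);
  std::vector<double> gw(p, 0.0);  // G %*% w, maintained incrementally
  std::vector<int> active;
  active.reserve(p);
  const double* Gp = REAL(G);

  for (int a = 0; a < na; ++a) {
    const double alpha = alphas[a];
    bool converged = false;
    int it = 0;

    // one coordinate update; returns the scaled change
    auto update = [&](int j) -> double {
      const double gjj = Gp[j * (R_xlen_t)p + j];
      if (gjj <= 0.0) {
        if (w[j] != 0.0) {
          const double d = -w[j];
          const double* col = Gp + (R_xlen_t)j * p;
          for (int k = 0; k < p; ++k) gw[k] += col[k] * d;
          w[j] = 0.0;
        }
        return 0.0;
      }
      const double rho = b[j] - gw[j] + gjj * w[j];
      double wj = 0.0;
      if (rho > alpha)       wj = (rho - alpha) / gjj;
      else if (rho < -alpha) wj = (rho + alpha) / gjj;
      const double d = wj - w[j];
      if (d != 0.0) {
        const double* col = Gp + (R_xlen_t)j * p;
        for (int k = 0; k < p; ++k) gw[k] += col[k] * d;
        w[j] = wj;
        return std::fabs(d) * std::sqrt(gjj);
      }
      return 0.0;
    };

    while (!converged && it < maxit) {
      // inner loop on the current active set
      active.clear();
      for (int j = 0; j < p; ++j) if (w[j] != 0.0) active.push_back(j);
      if (!active.empty()) {
        for (; it < maxit; ++it) {
          double maxdelta = 0.0;
          for (int j : active) {
            const double d = update(j);
            if (d > maxdelta) maxdelta = d;
          }
          if (maxdelta <= tol) break;
        }
      }
      // full sweep: converged only if nothing moves beyond tol
      double maxdelta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double d = update(j);
        if (d > maxdelta) maxdelta = d;
      }
      ++it;
      converged = (maxdelta <= tol);
    }
    if (!converged)
      warning("coordinate descent reached maxit without converging at alpha = %f",
              alpha);
    for (int j = 0; j < p; ++j) beta(j, a) = w[j];
  }
  return beta;
}
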