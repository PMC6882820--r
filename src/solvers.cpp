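// Coordinate-descent solvers for the two estimators that need compiled code:
// the graphical lasso (penalized precision estimation) and SPACE (joint
// sparse regression on shared partial-correlation parameters).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Graphical lasso, block coordinate descent over columns (each column update
// is a lasso problem on the current covariance estimate W).  The diagonal is
// not penalized: W keeps diag(S) throughout.  B stores, column by column, the
// regression weights of the column-update lasso problems; passing W and B
// back in gives warm starts along a regularization path.
//
// Objective: tr(S * Omega) - log det(Omega) + lambda * sum_{i != j} |omega_ij|
// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda, double tol, int maxit,
                     Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                     Rcpp::Nullable<Rcpp::NumericMatrix> B_init = R_NilValue) {
  const int p = S.n_rows;
  mat W(p, p), B(p, p, fill::zeros);
  if (W_init.isNotNull()) W = Rcpp::as<mat>(W_init.get()); else W = S;
  if (B_init.isNotNull()) B = Rcpp::as<mat>(B_init.get());
  W.diag() = S.diag();

  // convergence scale: average absolute off-diagonal entry of S
  double s_scale = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) s_scale += std::fabs(S(i, j));
  s_scale /= std::max(1, p * (p - 1));
  if (s_scale <= 0) s_scale = 1.0;
  const double thr = tol * s_scale;

  uvec all = regspace<uvec>(0, p - 1);
  int it = 0;
  bool converged = false;
  double dw = datum::inf;

  for (it = 0; it < maxit; ++it) {
    dw = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx = find(all != (unsigned) j);
      mat V = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec b = B.col(j);
      b = b.elem(idx);
      // coordinate descent on the column lasso
      for (int inner = 0; inner < 100; ++inner) {
        double db = 0.0;
        for (int l = 0; l < p - 1; ++l) {
          double r = s12(l) - dot(V.row(l), b) + V(l, l) * b(l);
          double bl = soft_threshold(r, lambda) / V(l, l);
          db = std::max(db, std::fabs(bl - b(l)));
          b(l) = bl;
        }
        if (db < thr) break;
      }
      vec w12 = V * b;
      for (int l = 0; l < p - 1; ++l) {
        double wnew = w12(l);
        dw += std::fabs(wnew - W(idx(l), j));
        W(idx(l), j) = wnew;
        W(j, idx(l)) = wnew;
      }
      vec bfull(p, fill::zeros);
      bfull.elem(idx) = b;
      B.col(j) = bfull;
    }
    dw /= std::max(1, p * (p - 1));  // mean absolute off-diagonal change
    if (dw < thr) { converged = true; break; }
  }

  // recover Omega from W and the column regression weights
  mat Omega(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx = find(all != (unsigned) j);
    vec b = B.col(j);
    b = b.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double ojj = 1.0 / (W(j, j) - dot(w12, b));
    Omega(j, j) = ojj;
    for (int l = 0; l < p - 1; ++l) Omega(idx(l), j) = -b(l) * ojj;
  }
  Omega = 0.5 * (Omega + Omega.t());

  return Rcpp::List::create(
      Rcpp::Named("omega") = Omega, Rcpp::Named("W") = W,
      Rcpp::Named("B") = B, Rcpp::Named("iterations") = it + 1,
      Rcpp::Named("converged") = converged, Rcpp::Named("delta") = dw);
}

static double space_objective(const mat& R, const mat& rho, double lambda) {
  double rss = 0.5 * accu(square(R));
  double pen = 0.0;
  const int p = rho.n_rows;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) pen += std::fabs(rho(i, j));
  return rss + lambda * pen;
}

static void space_residuals(const mat& X, const mat& rho, const vec& w,
                            mat& R) {
  const int p = X.n_cols;
  R = X;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j && rho(i, j) != 0.0)
        R.col(i) -= rho(i, j) * std::sqrt(w(j) / w(i)) * X.col(j);
}

// SPACE: alternate (a) coordinate descent on the shared rho_ij parameters
// with the residual precisions w_i = omega_ii fixed, and (b) w_i updated as
// inverse mean residual variances.  Each rho_ij coordinate update is a soft
// threshold of a residual inner product aggregated over the regressions of
// node i on j and node j on i.  The reported objective sequence is
// non-increasing: if a w-update pass raises the objective the previous
// iterate is returned.
//
// Objective: 0.5 * sum_i || X_i - sum_{j != i} rho_ij sqrt(w_j/w_i) X_j ||^2
//            + lambda * sum_{i<j} |rho_ij|
// [[Rcpp::export]]
Rcpp::List space_cd(const arma::mat& X, double lambda, double tol,
                    int max_outer,
                    Rcpp::Nullable<Rcpp::NumericMatrix> rho_init = R_NilValue,
                    Rcpp::Nullable<Rcpp::NumericVector> w_init = R_NilValue) {
  const int n = X.n_rows, p = X.n_cols;
  mat rho(p, p, fill::zeros);
  vec w(p);
  if (rho_init.isNotNull()) rho = Rcpp::as<mat>(rho_init.get());
  if (w_init.isNotNull()) w = Rcpp::as<vec>(w_init.get());
  else {
    for (int i = 0; i < p; ++i) w(i) = 1.0 / var(X.col(i));
  }
  vec cn(p);
  for (int j = 0; j < p; ++j) cn(j) = dot(X.col(j), X.col(j));

  mat R;
  space_residuals(X, rho, w, R);
  double obj = space_objective(R, rho, lambda);
  mat rho_best = rho; vec w_best = w; double obj_best = obj;

  int it = 0;
  bool converged = false;
  for (it = 0; it < max_outer; ++it) {
    // (a) coordinate descent on rho with w fixed
    for (int sweep = 0; sweep < 1000; ++sweep) {
      double dmax = 0.0;
      for (int i = 0; i < p; ++i) {
        for (int j = i + 1; j < p; ++j) {
          double fij = std::sqrt(w(j) / w(i));
          double fji = std::sqrt(w(i) / w(j));
          double c = fij * fij * cn(j) + fji * fji * cn(i);
          double u = fij * dot(X.col(j), R.col(i)) +
                     fji * dot(X.col(i), R.col(j)) + rho(i, j) * c;
          double rnew = soft_threshold(u, lambda) / c;
          double d = rnew - rho(i, j);
          if (d != 0.0) {
            R.col(i) -= d * fij * X.col(j);
            R.col(j) -= d * fji * X.col(i);
            rho(i, j) = rnew;
            rho(j, i) = rnew;
            dmax = std::max(dmax, std::fabs(d));
          }
        }
      }
      if (dmax < tol) break;
    }
    double obj_new = space_objective(R, rho, lambda);
    if (obj_new <= obj_best + 1e-12) { rho_best = rho; w_best = w; obj_best = obj_new; }
    if (std::fabs(obj - obj_new) < tol * std::max(1.0, std::fabs(obj))) {
      obj = obj_new;
      converged = true;
      break;
    }
    obj = obj_new;
    // (b) w update: inverse mean residual variance
    for (int i = 0; i < p; ++i) {
      double rss_i = dot(R.col(i), R.col(i));
      w(i) = (double) n / std::max(rss_i, 1e-300);
    }
    space_residuals(X, rho, w, R);
  }

  space_residuals(X, rho_best, w_best, R);
  vec rss(p);
  for (int i = 0; i < p; ++i) rss(i) = dot(R.col(i), R.col(i));

  return Rcpp::List::create(
      Rcpp::Named("rho") = rho_best, Rcpp::Named("w") = w_best,
      Rcpp::Named("rss") = rss, Rcpp::Named("objective") = obj_best,
      Rcpp::Named("iterations") = it + 1, Rcpp::Named("converged") = converged);
}
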