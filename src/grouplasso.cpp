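// Block coordinate descent for the group lasso and the two-condition joint
// nodewise regressions built on it.  The objective solved by gl_fit_cpp is
//
//   (1 / (2N)) * ||y - X b||_2^2 + lambda * sum_l w_l ||b_l||_2
//
// with per-group weights w_l (sqrt(p_l) by default, times any penalty
// factor supplied by the caller).  Blocks are updated by
// majorize-minimize: the group's quadratic term is majorized with the
// largest eigenvalue of X_l'X_l / N, giving a closed-form group
// soft-threshold update and monotone descent.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double group_update(const mat& X, const uvec& cols,
                                  double gam, double lw, double N,
                                  vec& beta, vec& r) {
  // current block
  vec b_old = beta.elem(cols);
  // z = gam * b_old + X_l' r / N
  vec z = gam * b_old + X.cols(cols).t() * r / N;
  double zn = norm(z, 2);
  vec b_new(b_old.n_elem, fill::zeros);
  if (zn > lw) b_new = z * ((1.0 - lw / zn) / gam);
  vec diff = b_new - b_old;
  double delta = norm(diff, "inf");
  if (delta > 0) {
    r -= X.cols(cols) * diff;
    beta.elem(cols) = b_new;
  }
  return delta;
}

// [[Rcpp::export]]
Rcpp::List gl_fit_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::ivec& grp, const arma::vec& w,
                      double lambda, arma::vec beta,
                      double tol, int maxit) {
  const double N = static_cast<double>(X.n_rows);
  const int L = w.n_elem;
  std::vector<uvec> cols(L);
  for (int l = 0; l < L; ++l) cols[l] = find(grp == l);

  // majorization constants: largest eigenvalue of X_l'X_l / N
  vec gam(L);
  for (int l = 0; l < L; ++l) {
    mat G = X.cols(cols[l]).t() * X.cols(cols[l]) / N;
    vec ev;
    eig_sym(ev, G);
    gam[l] = std::max(ev.max(), 1e-12);
  }

  vec r = y - X * beta;
  int it = 0;
  bool converged = false;
  for (; it < maxit; ++it) {
    double delta = 0.0;
    for (int l = 0; l < L; ++l) {
      double d = group_update(X, cols[l], gam[l], lambda * w[l], N, beta, r);
      if (d > delta) delta = d;
    }
    if (delta < tol) { converged = true; break; }
  }
  double obj = dot(r, r) / (2.0 * N);
  for (int l = 0; l < L; ++l) obj += lambda * w[l] * norm(beta.elem(cols[l]), 2);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("iterations") = it + 1,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("residual") = r);
}

// Joint nodewise regressions across two conditions.  For each node j the
// regression of column j on all other columns is solved in both conditions
// simultaneously, the two coefficients of each predictor forming one group
// with a sparse-group penalty:
//
//   sum_k (1/(2 n_k)) ||x_kj - X_k[,-j] b_k||^2
//     + lambda * sum_m [ mix * ||(b_1m, b_2m)||_1
//                        + (1 - mix) * w * ||(b_1m, b_2m)||_2 ]
//
// The 2-norm part couples the two conditions (shared structure is
// selected jointly); the elementwise part allows an edge to be present
// in one condition only.  The per-group Hessian is diagonal (the two
// conditions share no samples), so the majorization constant is
// max_k ||x_km||^2 / n_k and the block update is the sparse-group
// proximal map (componentwise soft threshold, then group shrinkage).
// Supports are AND-symmetrized per condition.  Lambdas must be
// descending; fits are warm-started along the path.
// [[Rcpp::export]]
Rcpp::List joint_nodewise_cpp(const arma::mat& X1, const arma::mat& X2,
                              const arma::vec& lambdas, double w,
                              double mix, double tol, int maxit) {
  const uword p = X1.n_cols;
  const double n1 = static_cast<double>(X1.n_rows);
  const double n2 = static_cast<double>(X2.n_rows);
  const uword nlam = lambdas.n_elem;

  // column norms^2 / n per condition
  rowvec c1 = sum(square(X1), 0) / n1;
  rowvec c2 = sum(square(X2), 0) / n2;

  ucube sel1(p, p, nlam, fill::zeros);  // sel(m, j, l): predictor m in regression j
  ucube sel2(p, p, nlam, fill::zeros);
  mat rss1(p, nlam), rss2(p, nlam);
  umat df1(p, nlam, fill::zeros), df2(p, nlam, fill::zeros);

  for (uword j = 0; j < p; ++j) {
    vec y1 = X1.col(j), y2 = X2.col(j);
    vec b1(p, fill::zeros), b2(p, fill::zeros);  // slot j stays zero
    vec r1 = y1, r2 = y2;
    for (uword li = 0; li < nlam; ++li) {
      double l1 = lambdas[li] * mix;            // elementwise threshold
      double lg = lambdas[li] * (1.0 - mix) * w; // group threshold
      bool converged = false;
      for (int it = 0; it < maxit; ++it) {
        double delta = 0.0;
        for (uword m = 0; m < p; ++m) {
          if (m == j) continue;
          double gam = std::max(std::max(c1[m], c2[m]), 1e-12);
          double z1 = gam * b1[m] + dot(X1.col(m), r1) / n1;
          double z2 = gam * b2[m] + dot(X2.col(m), r2) / n2;
          // sparse-group prox: soft threshold, then group shrinkage
          double s1 = std::fabs(z1) > l1 ? z1 - std::copysign(l1, z1) : 0.0;
          double s2 = std::fabs(z2) > l1 ? z2 - std::copysign(l1, z2) : 0.0;
          double sn = std::sqrt(s1 * s1 + s2 * s2);
          double nb1 = 0.0, nb2 = 0.0;
          if (sn > lg) {
            double s = (1.0 - lg / sn) / gam;
            nb1 = s1 * s; nb2 = s2 * s;
          }
          double d1 = nb1 - b1[m], d2 = nb2 - b2[m];
          double d = std::max(std::fabs(d1), std::fabs(d2));
          if (d > 0) {
            if (d1 != 0.0) r1 -= X1.col(m) * d1;
            if (d2 != 0.0) r2 -= X2.col(m) * d2;
            b1[m] = nb1; b2[m] = nb2;
            if (d > delta) delta = d;
          }
        }
        if (delta < tol) { converged = true; break; }
      }
      (void)converged;
      rss1(j, li) = dot(r1, r1);
      rss2(j, li) = dot(r2, r2);
      for (uword m = 0; m < p; ++m) {
        if (m == j) continue;
        if (b1[m] != 0.0) { sel1(m, j, li) = 1; df1(j, li) += 1; }
        if (b2[m] != 0.0) { sel2(m, j, li) = 1; df2(j, li) += 1; }
      }
    }
  }

  // AND symmetrization: edge (i,j) kept iff selected from both endpoints
  ucube supp1(p, p, nlam, fill::zeros), supp2(p, p, nlam, fill::zeros);
  for (uword li = 0; li < nlam; ++li) {
    for (uword i = 0; i < p; ++i) {
      for (uword j2 = i + 1; j2 < p; ++j2) {
        if (sel1(i, j2, li) && sel1(j2, i, li)) {
          supp1(i, j2, li) = 1; supp1(j2, i, li) = 1;
        }
        if (sel2(i, j2, li) && sel2(j2, i, li)) {
          supp2(i, j2, li) = 1; supp2(j2, i, li) = 1;
        }
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("support1") = supp1,
                            Rcpp::Named("support2") = supp2,
                            Rcpp::Named("rss1") = rss1,
                            Rcpp::Named("rss2") = rss2,
                            Rcpp::Named("df1") = df1,
                            Rcpp::Named("df2") = df2);
}
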