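#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Block coordinate descent for the cross-tissue sparse-group objective
//   sum_t (1/(2 n_t)) ||y_t - X_t b_t||^2
//     + lambda1 * sum_j ||b_j.||_2 + lambda2 * sum_{j,t} |b_jt|
// on per-tissue standardized predictors, parameterized by the Gram
// matrices G_t = X_t'X_t/n_t (unit diagonal) and c_t = X_t'y_t/n_t.
// [[Rcpp::export]]
arma::mat sgl_solve(const Rcpp::List& gram, const Rcpp::List& xty,
                    double lambda1, double lambda2, arma::mat beta,
                    int max_iter, double tol) {
  const int T = gram.size();
  const int p = beta.n_rows;
  std::vector<mat> G(T);
  std::vector<vec> c(T);
  std::vector<vec> q(T);  // G_t * beta_t, maintained incrementally
  for (int t = 0; t < T; ++t) {
    G[t] = Rcpp::as<mat>(gram[t]);
    c[t] = Rcpp::as<vec>(xty[t]);
    q[t] = G[t] * beta.col(t);
  }
  vec u(T), old(T);
  for (int it = 0; it < max_iter; ++it) {
    double maxdel = 0.0;
    for (int j = 0; j < p; ++j) {
      double unorm = 0.0;
      for (int t = 0; t < T; ++t) {
        old[t] = beta(j, t);
        double z = c[t][j] - q[t][j] + G[t](j, j) * old[t];
        u[t] = soft(z, lambda2);
        unorm += u[t] * u[t];
      }
      unorm = std::sqrt(unorm);
      double shrink = (unorm > lambda1) ? (1.0 - lambda1 / unorm) : 0.0;
      for (int t = 0; t < T; ++t) {
        double nb = shrink * u[t];
        double d = nb - old[t];
        if (d != 0.0) {
          q[t] += G[t].col(j) * d;
          beta(j, t) = nb;
          double ad = std::fabs(d);
          if (ad > maxdel) maxdel = ad;
        }
      }
    }
    if (maxdel < tol) break;
  }
  return beta;
}
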