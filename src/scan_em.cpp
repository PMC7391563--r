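// EM interval-mapping core: at each grid position, fit a 3-component
// normal mixture whose component weights are the HMM genotype
// probabilities, with optional additive or genotype-interactive
// covariates. LOD = log10 likelihood ratio against the covariate-only
// null. Kept in compiled code because permutation thresholds re-run the
// scan hundreds of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double null_loglik(const vec& y, const mat& Z) {
  mat X = join_horiz(ones<mat>(y.n_elem, 1), Z);
  vec beta = solve(X, y);
  vec r = y - X * beta;
  double n = (double) y.n_elem;
  double s2 = dot(r, r) / n;
  if (s2 < 1e-300) s2 = 1e-300;
  return -0.5 * n * (std::log(2.0 * M_PI * s2) + 1.0);
}

// [[Rcpp::export]]
Rcpp::List scan_em_cpp(const arma::cube& P, const arma::vec& y,
                       const arma::mat& Z, const bool interactive,
                       const double tol, const int maxit) {
  const uword n = y.n_elem, npos = P.n_slices, p = Z.n_cols;
  vec lod(npos), iters(npos, fill::zeros);
  const double ll0 = null_loglik(y, Z);
  double sd0 = stddev(y) * std::sqrt((double)(n - 1) / n);
  if (sd0 < 1e-12) sd0 = 1e-12;
  const uword q = 3 + (interactive ? 3 * p : p);
  const mat ZtZ = (p > 0) ? mat(Z.t() * Z) : mat();
  const vec Zty = (p > 0) ? vec(Z.t() * y) : vec();

  for (uword s = 0; s < npos; ++s) {
    const mat& Ps = P.slice(s);
    vec mu(3, fill::value(mean(y)));
    vec gam(q - 3, fill::zeros);
    double sigma = sd0;
    double ll_old = -datum::inf, ll = 0.0;
    mat W(n, 3);
    int it = 0;
    for (it = 0; it < maxit; ++it) {
      // E step at current parameters
      mat M(n, 3);
      for (int g = 0; g < 3; ++g) {
        vec shift(n, fill::zeros);
        if (p > 0)
          shift = interactive ? vec(Z * gam.subvec(g * p, g * p + p - 1))
                              : vec(Z * gam);
        M.col(g) = mu(g) + shift;
      }
      mat D(n, 3);
      const double c0 = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
      for (int g = 0; g < 3; ++g) {
        vec r = (y - M.col(g)) / sigma;
        D.col(g) = c0 * exp(-0.5 * square(r));
      }
      mat WP = Ps % D;
      vec rs = sum(WP, 1);
      rs.elem(find(rs < 1e-300)).fill(1e-300);
      ll = accu(log(rs));
      W = WP.each_col() / rs;
      if (std::abs(ll - ll_old) < tol) break;
      ll_old = ll;
      // M step: weighted least squares over the expanded design
      mat A(q, q, fill::zeros);
      vec b(q, fill::zeros);
      vec wg = sum(W, 0).t();
      for (int g = 0; g < 3; ++g) {
        A(g, g) = std::max(wg(g), 1e-12);
        b(g) = dot(W.col(g), y);
      }
      if (p > 0) {
        if (!interactive) {
          mat WtZ = W.t() * Z;  // 3 x p
          for (int g = 0; g < 3; ++g) {
            A.submat(g, 3, g, 3 + p - 1) = WtZ.row(g);
            A.submat(3, g, 3 + p - 1, g) = WtZ.row(g).t();
          }
          A.submat(3, 3, 3 + p - 1, 3 + p - 1) = ZtZ;  // row weights sum to 1
          b.subvec(3, 3 + p - 1) = Zty;
        } else {
          for (int g = 0; g < 3; ++g) {
            uword o = 3 + g * p;
            mat Zw = Z.each_col() % W.col(g);
            rowvec cs = sum(Zw, 0);
            A.submat(g, o, g, o + p - 1) = cs;
            A.submat(o, g, o + p - 1, g) = cs.t();
            A.submat(o, o, o + p - 1, o + p - 1) = Z.t() * Zw;
            b.subvec(o, o + p - 1) = Zw.t() * y;
          }
        }
      }
      vec theta;
      bool ok = solve(theta, A, b,
                      solve_opts::fast + solve_opts::no_approx);
      if (!ok) theta = pinv(A) * b;
      mu = theta.subvec(0, 2);
      if (q > 3) gam = theta.subvec(3, q - 1);
      double rss = 0.0;
      for (int g = 0; g < 3; ++g) {
        vec shift(n, fill::zeros);
        if (p > 0)
          shift = interactive ? vec(Z * gam.subvec(g * p, g * p + p - 1))
                              : vec(Z * gam);
        rss += dot(W.col(g), square(y - (mu(g) + shift)));
      }
      sigma = std::sqrt(rss / n);
      if (sigma < 1e-12) sigma = 1e-12;
    }
    lod(s) = (ll - ll0) / std::log(10.0);
    iters(s) = it;
  }
  return Rcpp::List::create(Rcpp::Named("lod") = lod,
                            Rcpp::Named("null_loglik") = ll0,
                            Rcpp::Named("iters") = iters);
}
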