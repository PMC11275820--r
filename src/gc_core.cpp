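#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Hot loops only: the user-facing Granger fits live in R (R/granger.R); the
// C++ paths here are recursions that would dominate runtime in interpreted
// code and are cross-checked against the R implementations in the test suite.

// VAR(P) recursion. coefs is a C x C x P cube, coefs.slice(p-1)(i, j) = effect
// of channel j at lag p+... on channel i. innov holds pre-drawn innovations
// (burn-in rows included); the caller discards the burn-in.
// [[Rcpp::export]]
arma::mat cpp_var_recursion(const arma::cube& coefs, const arma::mat& innov) {
  const arma::uword n = innov.n_rows;
  const arma::uword P = coefs.n_slices;
  arma::mat x = innov;  // starts as innovations, AR terms added in place
  for (arma::uword t = 0; t < n; ++t) {
    for (arma::uword p = 1; p <= P && p <= t; ++p) {
      x.row(t) += x.row(t - p) * coefs.slice(p - 1).t();
    }
  }
  return x;
}

// Through-the-origin least squares on a lagged design; returns residual sum
// of squares. Mirrors the conditional-OLS convention of R/granger.R: rows
// P+1..n are used, no intercept.
static double lagged_rss(const arma::vec& y, const arma::mat& X) {
  arma::vec b;
  bool ok = arma::solve(b, X, y, arma::solve_opts::no_approx);
  if (!ok) b = arma::pinv(X) * y;
  arma::vec r = y - X * b;
  return arma::dot(r, r);
}

// Granger-causality log variance ratio for source -> target on two short
// series of equal length, lag order P. Returns 0 for (near-)constant inputs:
// a flat window carries no predictive structure, so its attention score is
// floored rather than propagated as NaN.
static double gc_value_short(const arma::vec& target, const arma::vec& source,
                             const arma::uword P) {
  const arma::uword n = target.n_elem;
  if (n <= 3 * P) return NA_REAL;
  const arma::uword m = n - P;
  const double eps = 1e-12;
  if (arma::var(target) < eps || arma::var(source) < eps) return 0.0;

  arma::vec y = target.subvec(P, n - 1);
  arma::mat Xu(m, P), Xb(m, 2 * P);
  for (arma::uword p = 1; p <= P; ++p) {
    arma::vec own = target.subvec(P - p, n - 1 - p);
    Xu.col(p - 1) = own;
    Xb.col(p - 1) = own;
    Xb.col(P + p - 1) = source.subvec(P - p, n - 1 - p);
  }
  double rss_u = lagged_rss(y, Xu);
  double rss_b = lagged_rss(y, Xb);
  double gc = std::log((rss_u + 1e-300) / (rss_b + 1e-300));
  if (!std::isfinite(gc)) gc = 0.0;
  return gc;
}

// Score matrix of the Granger attention: Q and K are L x P x F cubes holding
// the per-timepoint window series of the (sub-sampled) query/key features.
// score(t, s) = mean over features f of GC(K[s, , f] -> Q[t, , f]) at the
// given lag. O(L^2 * F) small OLS fits; this is the cost hot spot.
// [[Rcpp::export]]
arma::mat cpp_gc_score_matrix(const arma::cube& Q, const arma::cube& K,
                              const int lag) {
  const arma::uword L = Q.n_rows;
  const arma::uword F = Q.n_slices;
  arma::mat scores(L, L, arma::fill::zeros);
  for (arma::uword t = 0; t < L; ++t) {
    for (arma::uword s = 0; s < L; ++s) {
      double acc = 0.0;
      for (arma::uword f = 0; f < F; ++f) {
        arma::vec q = Q.slice(f).row(t).t();
        arma::vec k = K.slice(f).row(s).t();
        acc += gc_value_short(q, k, (arma::uword)lag);
      }
      scores(t, s) = acc / (double)F;
    }
  }
  return scores;
}

// Single short-series GC value, exported for the attention oracle tests.
// [[Rcpp::export]]
double cpp_gc_value(const arma::vec& target, const arma::vec& source,
                    const int lag) {
  return gc_value_short(target, source, (arma::uword)lag);
}
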