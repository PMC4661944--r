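// Weighted least-squares founder-haplotype scan.
//
// The design at each marker is [1, dosage columns for the 7 non-reference
// founders]; the reference founder (WSB by convention) is omitted so that
// its effect is identically zero.  Because founder dosages sum to 2 at
// every marker, keeping all 8 columns plus an intercept would be exactly
// collinear.
//
// Tensors arrive as arma::cube with dimensions line x founder x marker.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double RANK_TOL = 1e-8;

// logP of the F test of the genetic model vs the weighted-mean null,
// clamped to [0, clamp]
static double f_logp(double rss0, double rss1, double df1, double df2,
                     double clamp) {
  if (df1 < 0.5) return 0.0;
  if (rss1 <= 0.0) {
    // perfect interpolation (possibly saturated): P underflows, clamp
    return (rss0 > 0.0) ? clamp : 0.0;
  }
  if (df2 < 0.5) return 0.0;
  if (rss0 <= rss1) return 0.0;
  double fstat = ((rss0 - rss1) / df1) / (rss1 / df2);
  double lp = -R::pf(fstat, df1, df2, 0, 1) / M_LN10;  // upper tail, log scale
  if (!std::isfinite(lp) || lp > clamp) lp = clamp;
  if (lp < 0.0) lp = 0.0;
  return lp;
}

// per-marker design, whitened by sqrt(w): columns = intercept, founders != ref
static void fill_design(const cube& P, uword m, uword ref, const vec& sw,
                        mat& X) {
  const uword n = P.n_rows, nf = P.n_cols;
  X.col(0) = sw;
  uword j = 1;
  for (uword f = 0; f < nf; ++f) {
    if (f == ref) continue;
    X.col(j++) = P.slice(m).col(f) % sw;
  }
}

// weighted RSS + coefficients for one whitened design
static void wls_fit(const mat& Xw, const vec& yw, double yty, vec& beta,
                    double& rss, uword& rank) {
  mat C = Xw.t() * Xw;
  vec b = Xw.t() * yw;
  bool ok = solve(beta, C, b, solve_opts::likely_sympd + solve_opts::no_approx);
  if (ok) {
    rank = Xw.n_cols;
  } else {
    // rank-deficient marker (e.g. founder never observed): minimum-norm fit
    beta = pinv(C, RANK_TOL) * b;
    rank = arma::rank(Xw, RANK_TOL * norm(Xw, "inf"));
  }
  rss = yty - dot(b, beta);
  if (rss < 0.0) rss = 0.0;
}

// [[Rcpp::export]]
Rcpp::List scan_wls_cpp(const arma::cube& P, const arma::vec& y,
                        const arma::vec& w, int ref1, double clamp) {
  const uword n = P.n_rows, m = P.n_slices, p = P.n_cols;  // p founders
  const uword ref = (uword)(ref1 - 1);
  vec sw = sqrt(w);
  double swsum = accu(w);
  double ybar = dot(w, y) / swsum;
  vec yc = y - ybar;                       // center for conditioning
  vec yw = yc % sw;
  double yty = dot(yw, yw);                // = null (intercept-only) RSS
  double rss0 = yty;

  vec logp(m), rss(m);
  uvec rank(m);
  mat beta(p, m, fill::zeros);             // founder effects, ref row = 0
  vec icept(m);
  mat Xw(n, p);
  vec bhat;
  double r1;
  uword rk;

  for (uword k = 0; k < m; ++k) {
    fill_design(P, k, ref, sw, Xw);
    wls_fit(Xw, yw, yty, bhat, r1, rk);
    rss(k) = r1;
    rank(k) = rk;
    double df1 = (double)rk - 1.0, df2 = (double)n - (double)rk;
    logp(k) = f_logp(rss0, r1, df1, df2, clamp);
    icept(k) = bhat(0) + ybar;
    uword j = 1;
    for (uword f = 0; f < p; ++f) {
      if (f == ref) continue;
      beta(f, k) = bhat(j++);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("logp") = logp, Rcpp::Named("rss") = rss,
      Rcpp::Named("rss_null") = rss0, Rcpp::Named("rank") = rank,
      Rcpp::Named("beta") = beta, Rcpp::Named("intercept") = icept);
}

// Max logP over the genome for each permutation of (y, w) rows.
// perms: n x n_perm matrix of 1-based row indices drawn in R so that all
// randomness stays under R's seed control.
// [[Rcpp::export]]
arma::vec perm_max_logp_cpp(const arma::cube& P, const arma::vec& y,
                            const arma::vec& w, const arma::umat& perms,
                            int ref1, double clamp) {
  const uword n = P.n_rows, m = P.n_slices, p = P.n_cols;
  const uword ref = (uword)(ref1 - 1);
  const uword nperm = perms.n_cols;

  // raw (unwhitened) designs once
  std::vector<mat> X(m);
  for (uword k = 0; k < m; ++k) {
    mat Xk(n, p);
    Xk.col(0).ones();
    uword j = 1;
    for (uword f = 0; f < p; ++f) {
      if (f == ref) continue;
      Xk.col(j++) = P.slice(k).col(f);
    }
    X[k] = Xk;
  }

  vec out(nperm);
  vec bhat;
  double r1;
  uword rk;
  for (uword q = 0; q < nperm; ++q) {
    uvec idx = perms.col(q) - 1;
    vec yp = y(idx), wp = w(idx);
    vec swp = sqrt(wp);
    double ybar = dot(wp, yp) / accu(wp);
    vec ywp = (yp - ybar) % swp;
    double yty = dot(ywp, ywp);
    double best = 0.0;
    for (uword k = 0; k < m; ++k) {
      mat Xw = X[k].each_col() % swp;
      wls_fit(Xw, ywp, yty, bhat, r1, rk);
      double df1 = (double)rk - 1.0, df2 = (double)n - (double)rk;
      double lp = f_logp(yty, r1, df1, df2, clamp);
      if (lp > best) best = lp;
    }
    out(q) = best;
  }
  return out;
}
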