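// Profiled-deviance fitter for the single random-intercept linear mixed
// model y = X beta + u[group] + e, u ~ N(0, tau2), e ~ N(0, sigma2).
//
// With lambda = tau2/sigma2 the marginal covariance is sigma2 * (I +
// lambda * J) block-diagonal over groups, so the profiled ML/REML
// criterion is one-dimensional in lambda and every evaluation only needs
// per-group sums of X and y.  Group sums are pooled by distinct group
// size, making each criterion evaluation O(#sizes * p^2) after an
// O(n p^2) setup.  This is what makes family-level case bootstraps with
// hundreds of refits per model cell affordable; agreement with lme4 is
// asserted in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct RiSuff {
  mat XtX;       // p x p
  vec Xty;       // p
  double yty;
  uword n, p, ngrp;
  // pooled by distinct group size
  std::vector<double> sizes;      // distinct n_j
  std::vector<double> counts;     // number of groups of that size
  std::vector<mat> G;             // sum over groups of that size of s_j s_j'
  std::vector<vec> h;             // sum of s_j * t_j  (t_j = group sum of y)
  std::vector<double> q;          // sum of t_j^2
};

// Build sufficient statistics; group is 0-based, contiguous not required
// beyond max index = ngrp - 1.
void ri_suff(const mat& X, const vec& y, const uvec& group, uword ngrp,
             RiSuff& S) {
  const uword n = X.n_rows, p = X.n_cols;
  S.XtX = X.t() * X;
  S.Xty = X.t() * y;
  S.yty = dot(y, y);
  S.n = n; S.p = p; S.ngrp = ngrp;

  mat Sx(ngrp, p, fill::zeros);
  vec Sy(ngrp, fill::zeros);
  vec nj(ngrp, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    uword g = group[i];
    Sx.row(g) += X.row(i);
    Sy[g] += y[i];
    nj[g] += 1.0;
  }

  std::map<long, std::vector<uword>> by_size;
  for (uword j = 0; j < ngrp; ++j)
    if (nj[j] > 0) by_size[(long)nj[j]].push_back(j);

  S.sizes.clear(); S.counts.clear(); S.G.clear(); S.h.clear(); S.q.clear();
  for (auto& kv : by_size) {
    mat Gk(p, p, fill::zeros);
    vec hk(p, fill::zeros);
    double qk = 0.0;
    for (uword j : kv.second) {
      vec s = Sx.row(j).t();
      Gk += s * s.t();
      hk += s * Sy[j];
      qk += Sy[j] * Sy[j];
    }
    S.sizes.push_back((double)kv.first);
    S.counts.push_back((double)kv.second.size());
    S.G.push_back(Gk);
    S.h.push_back(hk);
    S.q.push_back(qk);
  }
}

// Criterion (ML deviance or REML criterion) at lambda; optionally returns
// the GLS pieces at that lambda.
double ri_crit(const RiSuff& S, double lam, bool reml,
               vec* beta_out = nullptr, mat* A_out = nullptr,
               double* sigma2_out = nullptr, double* ldetV_out = nullptr,
               bool* ok_out = nullptr) {
  const double n = (double)S.n, p = (double)S.p;
  mat A = S.XtX;
  vec b = S.Xty;
  double qq = S.yty;
  double ldetV = 0.0;
  for (size_t s = 0; s < S.sizes.size(); ++s) {
    double k = S.sizes[s];
    double w = lam / (1.0 + k * lam);
    A -= w * S.G[s];
    b -= w * S.h[s];
    qq -= w * S.q[s];
    ldetV += S.counts[s] * std::log1p(k * lam);
  }
  vec beta;
  bool ok = solve(beta, A, b, solve_opts::no_approx);
  if (!ok || !beta.is_finite()) {
    if (ok_out) *ok_out = false;
    return datum::inf;
  }
  double rss = qq - dot(beta, b);
  if (rss <= 0) rss = 1e-300;
  double crit;
  double sigma2;
  if (reml) {
    double sign, ldA;
    log_det(ldA, sign, A);
    sigma2 = rss / (n - p);
    crit = (n - p) * std::log(2.0 * datum::pi * sigma2) + ldetV + ldA +
           (n - p);
  } else {
    sigma2 = rss / n;
    crit = n * std::log(2.0 * datum::pi * sigma2) + ldetV + n;
  }
  if (beta_out) *beta_out = beta;
  if (A_out) *A_out = A;
  if (sigma2_out) *sigma2_out = sigma2;
  if (ldetV_out) *ldetV_out = ldetV;
  if (ok_out) *ok_out = true;
  return crit;
}

// Golden-section minimisation of the criterion over t = log(lambda) on
// [-14, 14], plus the lambda = 0 boundary.  Unimodality holds for this
// profiled criterion in practice; the boundary check covers tau2 -> 0.
double ri_opt_lambda(const RiSuff& S, bool reml) {
  const double lo = -14.0, hi = 14.0;
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double c = b - gr * (b - a);
  double d = a + gr * (b - a);
  double fc = ri_crit(S, std::exp(c), reml);
  double fd = ri_crit(S, std::exp(d), reml);
  for (int it = 0; it < 60; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = ri_crit(S, std::exp(c), reml);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = ri_crit(S, std::exp(d), reml);
    }
    if (b - a < 1e-7) break;
  }
  double t = (fc < fd) ? c : d;
  double lam = std::exp(t);
  double f_int = std::min(fc, fd);
  double f0 = ri_crit(S, 0.0, reml);
  return (f0 <= f_int) ? 0.0 : lam;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List ri_lmm_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::uvec& group, int ngrp, bool reml) {
  RiSuff S;
  ri_suff(X, y, group, (uword)ngrp, S);
  double lam = ri_opt_lambda(S, reml);

  vec beta; mat A; double sigma2, ldetV; bool ok = true;
  double crit = ri_crit(S, lam, reml, &beta, &A, &sigma2, &ldetV, &ok);
  if (!ok) Rcpp::stop("singular weighted design in mixed-model fit");
  mat Ainv = inv_sympd(symmatu(A));
  vec se = sqrt(sigma2 * Ainv.diag());

  // full ML log-likelihood at the (reml- or ml-) selected lambda
  vec beta_ml; double sigma2_ml;
  ri_crit(S, lam, false, &beta_ml, nullptr, &sigma2_ml, nullptr, &ok);
  double n = (double)S.n;
  double loglik_ml =
      -0.5 * (n * std::log(2.0 * datum::pi * sigma2_ml) + ldetV + n);

  return Rcpp::List::create(
      Rcpp::Named("beta") = beta, Rcpp::Named("se") = se,
      Rcpp::Named("vcov") = sigma2 * Ainv, Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("tau2") = lam * sigma2, Rcpp::Named("lambda") = lam,
      Rcpp::Named("loglik_ml") = loglik_ml, Rcpp::Named("crit") = crit,
      Rcpp::Named("reml") = reml);
}

// Family-level case bootstrap: resample ngrp groups with replacement
// (uses R's RNG, so set.seed() on the R side makes it reproducible),
// refit, and return the B x p matrix of coefficient draws (NaN rows for
// degenerate resamples).
// [[Rcpp::export]]
arma::mat ri_boot_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::uvec& group, int ngrp, int B, bool reml) {
  const uword n = X.n_rows, p = X.n_cols;
  std::vector<std::vector<uword>> rows((size_t)ngrp);
  for (uword i = 0; i < n; ++i) rows[group[i]].push_back(i);

  mat out(B, p);
  out.fill(datum::nan);
  Rcpp::RNGScope scope;

  std::vector<uword> idx;
  idx.reserve(2 * n);
  std::vector<uword> grp;
  grp.reserve(2 * n);

  for (int b = 0; b < B; ++b) {
    idx.clear(); grp.clear();
    for (int j = 0; j < ngrp; ++j) {
      int pick = (int)(unif_rand() * ngrp);
      if (pick >= ngrp) pick = ngrp - 1;
      for (uword r : rows[(size_t)pick]) {
        idx.push_back(r);
        grp.push_back((uword)j);
      }
    }
    uword nb = idx.size();
    mat Xb(nb, p);
    vec yb(nb);
    uvec gb(nb);
    for (uword i = 0; i < nb; ++i) {
      Xb.row(i) = X.row(idx[i]);
      yb[i] = y[idx[i]];
      gb[i] = grp[i];
    }
    RiSuff S;
    ri_suff(Xb, yb, gb, (uword)ngrp, S);
    double lam = ri_opt_lambda(S, reml);
    vec beta; bool ok = true;
    double sigma2;
    ri_crit(S, lam, reml, &beta, nullptr, &sigma2, nullptr, &ok);
    if (ok && beta.is_finite()) out.row(b) = beta.t();
  }
  return out;
}
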