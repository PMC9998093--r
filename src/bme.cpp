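// Dual solver for Bayesian/maximum-entropy ensemble reweighting.
//
// Primal problem: over the probability simplex, minimise
//   L(w) = 0.5 * sum_j (<I_j>_w - Iexp_j)^2 / sigma_j^2 + theta * KL(w || w0)
// (equivalently (m/2) chi2_r - theta * S_rel). Its dual in one multiplier
// per observable is smooth, unconstrained and convex:
//   Gamma(lambda) = theta * log Z(lambda) + sum_j lambda_j Iexp_j
//                   + 0.5 * sum_j lambda_j^2 sigma_j^2,
//   with w_k(lambda) = w0_k exp(-(1/theta) sum_j lambda_j I_jk) / Z.
// Positivity and normalisation of w hold by construction. Solved by damped
// Newton with a gradient-descent fallback.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double gamma_obj(const mat& I, const vec& w0log, const vec& Iexp,
                        const vec& sig2, double theta, const vec& lambda,
                        vec& w, double& logZ) {
  // w_k proportional to exp(log w0_k - (I lambda)_k / theta)
  vec a = w0log - (I * lambda) / theta;
  double amax = a.max();
  vec e = exp(a - amax);
  double s = accu(e);
  w = e / s;
  logZ = amax + std::log(s);
  return theta * logZ + dot(lambda, Iexp) + 0.5 * dot(square(lambda), sig2);
}

// [[Rcpp::export]]
Rcpp::List bme_dual_solve(const arma::mat& I,      // n x m conformer intensities
                          const arma::vec& w0,     // prior weights, sum 1
                          const arma::vec& Iexp,   // target intensities, length m
                          const arma::vec& sigma,  // target uncertainties
                          double theta,
                          const arma::vec& lambda0,
                          double gtol = 1e-10,
                          int maxit = 10000) {
  const uword m = I.n_cols;
  vec sig2 = square(sigma);
  vec w0log = log(clamp(w0, 1e-300, datum::inf));
  vec lambda = lambda0;
  vec w(I.n_rows);
  double logZ = 0.0;
  double f = gamma_obj(I, w0log, Iexp, sig2, theta, lambda, w, logZ);
  bool converged = false;
  int it = 0;
  // scale-aware gradient tolerance: gradient entries are in intensity units
  double gscale = std::max(1.0, norm(Iexp, "inf"));
  for (it = 0; it < maxit; ++it) {
    vec Ibar = I.t() * w;                       // <I_j>_w
    vec g = Iexp - Ibar + lambda % sig2;        // gradient of Gamma
    if (norm(g, "inf") <= gtol * gscale) { converged = true; break; }
    // Hessian: (1/theta) Cov_w(I) + diag(sig2)
    mat Iw = I.each_col() % w;
    mat H = (I.t() * Iw - Ibar * Ibar.t()) / theta;
    H.diag() += sig2;
    vec step;
    bool ok = solve(step, H, -g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok || !step.is_finite()) step = -g / gscale;
    // backtracking line search
    double t = 1.0;
    double gTs = dot(g, step);
    if (gTs > 0) { step = -g / gscale; gTs = dot(g, step); }
    vec wtry(w.n_rows);
    double ltry = 0.0, ftry = 0.0;
    double f_before = f;
    bool accepted = false;
    for (int ls = 0; ls < 60; ++ls) {
      vec lam_try = lambda + t * step;
      ftry = gamma_obj(I, w0log, Iexp, sig2, theta, lam_try, wtry, ltry);
      if (std::isfinite(ftry) && ftry <= f + 1e-4 * t * gTs) {
        lambda = lam_try; w = wtry; logZ = ltry; f = ftry;
        accepted = true;
        break;
      }
      t *= 0.5;
    }
    bool stalled = !accepted || (f_before - f <= 1e-13 * (std::abs(f_before) + 1.0));
    if (stalled) {
      // objective is at the precision floor; accept the solution if the
      // gradient is small on the problem's scale
      vec Ibar2 = I.t() * w;
      vec g2 = Iexp - Ibar2 + lambda % sig2;
      converged = norm(g2, "inf") <= 1e-6 * gscale;
      break;
    }
  }
  vec Ibar = I.t() * w;
  double chi2r = accu(square(Ibar - Iexp) / sig2) / double(m);
  // S_rel = -sum_k w_k log(w_k/w0_k); in the dual,
  // log(w_k/w0_k) = -(I lambda)_k / theta - log Z
  vec logratio = -(I * lambda) / theta - logZ;
  double S_rel = -dot(w, logratio);
  return Rcpp::List::create(
    Rcpp::Named("w") = w,
    Rcpp::Named("lambda") = lambda,
    Rcpp::Named("chi2r") = chi2r,
    Rcpp::Named("S_rel") = S_rel,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
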