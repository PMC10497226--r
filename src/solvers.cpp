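// Difference-of-convex solver for l0-constrained nodewise regressions.
//
// The column problem is
//   min_v ||y - X v||^2  s.t.  ||v_pen||_0 <= kappa,
// attacked through the truncated-L1 surrogate J(z; tau) = min(|z|/tau, 1):
// at each DC iteration the concave part is majorized at the current
// iterate, leaving the weighted Lasso
//   min_v ||y - X v||^2 + 2 n gamma tau sum_l w_l |v_l|,
// with w_l = I(|v_l^{t}| <= tau) on penalized coordinates. Everything is
// parameterized by the Gram quantities (X'X, X'y, y'y) so repeated calls
// on one data set are cheap.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft_threshold(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

// One full cycle of coordinate descent; returns max coordinate change.
static double cd_sweep(const arma::mat& XtX, const arma::vec& Xty,
                       const arma::vec& lam, arma::vec& v,
                       arma::vec& grad_cache) {
  const arma::uword q = Xty.n_elem;
  double max_change = 0.0;
  for (arma::uword l = 0; l < q; ++l) {
    double d = XtX(l, l);
    if (d <= 0.0) { v(l) = 0.0; continue; }  // degenerate (zero-variance) column
    // partial residual correlation r_l = Xty_l - sum_{m != l} XtX_lm v_m
    double r = Xty(l) - arma::dot(XtX.col(l), v) + d * v(l);
    double vnew = soft_threshold(r, lam(l)) / d;
    double change = std::fabs(vnew - v(l));
    if (change > max_change) max_change = change;
    v(l) = vnew;
  }
  (void)grad_cache;
  return max_change;
}

static double lasso_objective(const arma::mat& XtX, const arma::vec& Xty,
                              double yty, const arma::vec& lam,
                              const arma::vec& v) {
  return yty - 2.0 * arma::dot(v, Xty) + arma::dot(v, XtX * v) +
         2.0 * arma::dot(lam, arma::abs(v));
}

// [[Rcpp::export]]
List cpp_weighted_lasso(const arma::mat& XtX, const arma::vec& Xty,
                        double yty, const arma::vec& lam,
                        const arma::vec& start, double cd_tol,
                        int max_sweeps, bool trace_objective) {
  arma::vec v = start;
  arma::vec dummy;
  std::vector<double> obj;
  if (trace_objective) obj.push_back(lasso_objective(XtX, Xty, yty, lam, v));
  int sweeps = 0;
  for (; sweeps < max_sweeps; ) {
    double change = cd_sweep(XtX, Xty, lam, v, dummy);
    ++sweeps;
    if (trace_objective) obj.push_back(lasso_objective(XtX, Xty, yty, lam, v));
    if (change <= cd_tol) break;
  }
  return List::create(_["coef"] = v, _["sweeps"] = sweeps,
                      _["objective"] = obj);
}

// l0 projection onto the penalized coordinates: keep the kappa largest
// |entries| (ties -> lower index), free coordinates always kept.
static arma::uvec project_support(const arma::vec& v, const arma::uvec& pen,
                                  int kappa) {
  std::vector<arma::uword> keep;
  std::vector<std::pair<double, arma::uword>> cand;
  for (arma::uword l = 0; l < v.n_elem; ++l) {
    if (pen(l) == 0) {
      keep.push_back(l);
    } else if (v(l) != 0.0) {
      cand.push_back(std::make_pair(-std::fabs(v(l)), l));
    }
  }
  std::stable_sort(cand.begin(), cand.end());   // by -|v|, then lower index
  const int m = std::min<int>(kappa, (int)cand.size());
  for (int i = 0; i < m; ++i) keep.push_back(cand[i].second);
  std::sort(keep.begin(), keep.end());
  return arma::uvec(keep);
}

// OLS refit on a support; returns refit coefficients and RSS.
static void refit_ols(const arma::mat& XtX, const arma::vec& Xty, double yty,
                      const arma::uvec& supp, arma::vec& coef, double& rss) {
  coef.zeros(Xty.n_elem);
  if (supp.n_elem == 0) { rss = yty; return; }
  arma::mat G = XtX.submat(supp, supp);
  arma::vec b;
  bool ok = arma::solve(b, G, Xty.elem(supp), arma::solve_opts::no_approx);
  if (!ok) b = arma::pinv(G) * Xty.elem(supp);  // collinear support
  coef.elem(supp) = b;
  rss = yty - 2.0 * arma::dot(b, Xty.elem(supp)) + arma::dot(b, G * b);
  if (rss < 0.0) rss = 0.0;
}

// [[Rcpp::export]]
List cpp_dc_column(const arma::mat& XtX, const arma::vec& Xty, double yty,
                   int n, int kappa, double tau,
                   const arma::vec& gamma_grid, double tol, int max_dc_iter,
                   const arma::uvec& pen_mask, const arma::vec& dc_start,
                   double df_penalty, double cd_tol, int max_sweeps) {
  const arma::uword q = Xty.n_elem;
  arma::vec cd_warm = dc_start;         // warm start carried across the grid
  arma::vec lam(q);

  double best_score = arma::datum::inf;
  arma::vec best_coef(q, arma::fill::zeros);
  arma::vec best_vtilde(q, arma::fill::zeros);
  double best_rss = yty;
  int best_iters = 0;
  double best_gamma = gamma_grid(0);
  arma::uvec best_supp;
  std::vector<double> scores(gamma_grid.n_elem);

  for (arma::uword r = 0; r < gamma_grid.n_elem; ++r) {
    const double gamma = gamma_grid(r);
    arma::vec vt = dc_start;            // DC iterate starts at the given point
    int iters = 0;
    arma::uvec prev_active(q, arma::fill::zeros);
    for (int t = 0; t < max_dc_iter; ++t) {
      // the DC fixed point is reached once the truncation weight set
      // repeats: the next weighted-Lasso problem would be identical
      arma::uvec active(q);
      for (arma::uword l = 0; l < q; ++l) {
        active(l) = (pen_mask(l) && std::fabs(vt(l)) <= tau) ? 1 : 0;
        lam(l) = active(l) ? (double)n * gamma * tau : 0.0;
      }
      if (t > 0 && arma::all(active == prev_active)) break;
      prev_active = active;
      arma::vec vnext = (t == 0) ? cd_warm : vt;
      arma::vec dummy;
      for (int s = 0; s < max_sweeps; ++s) {
        if (cd_sweep(XtX, Xty, lam, vnext, dummy) <= cd_tol) break;
      }
      if (arma::abs(vnext - vt).max() <= tol) break;
      vt = vnext;
      iters = t + 1;
    }
    cd_warm = vt;

    arma::uvec supp = project_support(vt, pen_mask, kappa);
    // guard: refit cannot use more regressors than observations
    if ((int)supp.n_elem >= n) {
      arma::uvec trimmed = supp.subvec(0, std::max(0, n - 2));
      supp = trimmed;
    }
    arma::vec coef;
    double rss;
    refit_ols(XtX, Xty, yty, supp, coef, rss);
    double score = (double)n * std::log(std::max(rss, 1e-300) / n) +
                   (double)supp.n_elem * df_penalty;
    scores[r] = score;
    // ties resolve to the smallest gamma: identical refit, least shrinkage
    if (score <= best_score) {
      best_score = score;
      best_coef = coef;
      best_vtilde = vt;
      best_rss = rss;
      best_iters = iters;
      best_gamma = gamma;
      best_supp = supp;
    }
  }

  return List::create(_["coef"] = best_coef,
                      _["vtilde"] = best_vtilde,
                      _["support"] = IntegerVector(best_supp.begin(), best_supp.end()),
                      _["rss"] = best_rss,
                      _["iterations"] = best_iters,
                      _["gamma"] = best_gamma,
                      _["score"] = best_score,
                      _["scores"] = scores);
}
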