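// Hot-path numerics for the Monte-Carlo study: logistic IRLS, weighted
// difference-of-means estimators, all-subsets AIC enumeration, lasso
// coordinate descent with cross-validation, and their bootstrap loops.
// All randomness comes from R's RNG (unif_rand) so results are governed
// entirely by set.seed() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PS_EPS = 1e-10;   // keep fitted scores strictly in (0,1)
static const double SEP_COEF = 50.0;  // |beta| beyond this => treat as separation

// ---------------------------------------------------------------------------
// Logistic regression by iteratively reweighted least squares.
// D must already contain the intercept column. Returns false on failure
// (non-convergence or diverging coefficients, i.e. separation).
static bool irls_logistic(const arma::mat& D, const arma::vec& z,
                          arma::vec& beta, arma::vec& p,
                          double tol = 1e-8, int maxit = 100) {
  const arma::uword k = D.n_cols;
  beta.zeros(k);
  double dev_old = std::numeric_limits<double>::infinity();
  bool converged = false;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = D * beta;
    p = 1.0 / (1.0 + arma::exp(-eta));
    p = arma::clamp(p, PS_EPS, 1.0 - PS_EPS);
    arma::vec w = p % (1.0 - p);
    arma::vec wresp = eta + (z - p) / w;          // working response
    arma::mat Dw = D.each_col() % w;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, D.t() * Dw, Dw.t() * wresp,
                          arma::solve_opts::no_approx);
    if (!ok) return false;
    beta = beta_new;
    double dev = -2.0 * arma::accu(z % arma::log(p) +
                                   (1.0 - z) % arma::log(1.0 - p));
    if (std::abs(dev - dev_old) / (std::abs(dev) + 0.1) < tol) {
      converged = true;
      // one final update of fitted values at the converged beta
      eta = D * beta;
      p = arma::clamp(1.0 / (1.0 + arma::exp(-eta)), PS_EPS, 1.0 - PS_EPS);
      break;
    }
    dev_old = dev;
  }
  if (!converged) return false;
  if (arma::abs(beta).max() > SEP_COEF) return false;
  // a (near-)perfect fit only happens under complete separation
  double dev = -2.0 * arma::accu(z % arma::log(p) +
                                 (1.0 - z) % arma::log(1.0 - p));
  if (dev < 1e-6) return false;
  return true;
}

// [[Rcpp::export]]
List cpp_logit_fit(const arma::mat& D, const arma::vec& z,
                   double tol = 1e-8, int maxit = 100) {
  arma::vec beta, p;
  bool ok = irls_logistic(D, z, beta, p, tol, maxit);
  if (!ok) { beta.zeros(D.n_cols); p.zeros(D.n_rows); }
  return List::create(_["coefficients"] = beta,
                      _["fitted"] = p,
                      _["converged"] = ok);
}

// Hajek-normalized weighted mean differences for IPW and OW given scores e.
static arma::vec2 ipw_ow_from_scores(const arma::vec& y, const arma::vec& z,
                                     const arma::vec& e) {
  arma::vec w1 = z / e, w0 = (1.0 - z) / (1.0 - e);
  double ipw = arma::dot(w1, y) / arma::accu(w1) -
               arma::dot(w0, y) / arma::accu(w0);
  arma::vec v1 = z % (1.0 - e), v0 = (1.0 - z) % e;
  double ow = arma::dot(v1, y) / arma::accu(v1) -
              arma::dot(v0, y) / arma::accu(v0);
  arma::vec2 out; out(0) = ipw; out(1) = ow;
  return out;
}

// Fit the PS model on [1 X] and return c(ipw, ow); NaN on failed fit.
static arma::vec2 ipw_ow_point(const arma::vec& y, const arma::vec& z,
                               const arma::mat& X) {
  arma::vec2 bad; bad.fill(arma::datum::nan);
  double nz = arma::accu(z);
  if (nz < 1.0 || nz > z.n_elem - 1.0) return bad;
  arma::mat D(X.n_rows, X.n_cols + 1);
  D.col(0).ones();
  D.cols(1, X.n_cols) = X;
  arma::vec beta, e;
  if (!irls_logistic(D, z, beta, e)) return bad;
  return ipw_ow_from_scores(y, z, e);
}

// [[Rcpp::export]]
NumericVector cpp_ipw_ow(const arma::vec& y, const arma::vec& z,
                         const arma::mat& X) {
  arma::vec2 est = ipw_ow_point(y, z, X);
  return NumericVector::create(_["ipw"] = est(0), _["ow"] = est(1));
}

// draw a bootstrap index vector (0-based) using R's RNG
static arma::uvec boot_index(arma::uword n) {
  arma::uvec idx(n);
  for (arma::uword i = 0; i < n; ++i)
    idx(i) = (arma::uword)(unif_rand() * n);
  return idx;
}

// [[Rcpp::export]]
arma::mat cpp_boot_ipw_ow(const arma::vec& y, const arma::vec& z,
                          const arma::mat& X, int n_boot,
                          int max_redraw = 100) {
  arma::mat out(n_boot, 2);
  for (int b = 0; b < n_boot; ++b) {
    arma::vec2 est; est.fill(arma::datum::nan);
    for (int r = 0; r < max_redraw; ++r) {
      arma::uvec idx = boot_index(y.n_elem);
      est = ipw_ow_point(y(idx), z(idx), X.rows(idx));
      if (est.is_finite()) break;
    }
    out(b, 0) = est(0);
    out(b, 1) = est(1);
  }
  return out;
}

// ---------------------------------------------------------------------------
// All-subsets AIC over candidate predictors D (no intercept column; the
// intercept is always included). Gaussian AIC matching stats::AIC(lm):
//   AIC = n log(2*pi*RSS/n) + n + 2 * (q + 2)
// where q is the number of slopes (the +2 counts intercept and sigma^2).
// Subsets are visited in order of increasing size so that AIC ties resolve
// toward fewer parameters. Returns the coefficient of column `target`
// (0-based) in the minimum-AIC model, 0 if excluded.
struct AicBest {
  double aic, coef_target;
  unsigned int mask;
  bool any;
};

static AicBest aic_enumerate(const arma::vec& y, const arma::mat& D,
                             int target) {
  const arma::uword n = y.n_elem, p = D.n_cols;
  arma::mat F(n, p + 1);
  F.col(0).ones();
  F.cols(1, p) = D;
  arma::mat G = F.t() * F;
  arma::vec g = F.t() * y;
  double yty = arma::dot(y, y);
  const unsigned int nmask = 1u << p;
  // masks sorted by popcount (stable within size)
  std::vector<unsigned int> order(nmask);
  for (unsigned int m = 0; m < nmask; ++m) order[m] = m;
  std::stable_sort(order.begin(), order.end(),
                   [](unsigned int a, unsigned int b) {
                     int ca = __builtin_popcount(a), cb = __builtin_popcount(b);
                     return ca < cb;
                   });
  AicBest best; best.aic = arma::datum::inf; best.coef_target = 0.0;
  best.mask = 0u; best.any = false;
  for (unsigned int mi = 0; mi < nmask; ++mi) {
    unsigned int m = order[mi];
    arma::uvec idx(1 + (arma::uword)__builtin_popcount(m));
    idx(0) = 0;
    arma::uword k = 1;
    for (arma::uword j = 0; j < p; ++j)
      if (m & (1u << j)) idx(k++) = j + 1;
    arma::vec b;
    if (!arma::solve(b, G.submat(idx, idx), g(idx),
                     arma::solve_opts::no_approx)) continue;
    double rss = yty - arma::dot(b, g(idx));
    if (rss < 1e-12) rss = 1e-12;
    double aic = n * std::log(2.0 * M_PI * rss / n) + n + 2.0 * (idx.n_elem + 1.0);
    if (aic < best.aic) {
      best.aic = aic;
      best.mask = m;
      best.any = true;
      best.coef_target = 0.0;
      if (target >= 0 && (m & (1u << target))) {
        // locate target's position in idx
        for (arma::uword j = 1; j < idx.n_elem; ++j)
          if (idx(j) == (arma::uword)(target + 1)) { best.coef_target = b(j); break; }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_aic_best(const arma::vec& y, const arma::mat& D, int target = 0) {
  AicBest best = aic_enumerate(y, D, target);
  LogicalVector sel(D.n_cols);
  for (arma::uword j = 0; j < D.n_cols; ++j)
    sel[j] = (best.mask & (1u << j)) != 0;
  return List::create(_["coef_target"] = best.coef_target,
                      _["aic"] = best.aic,
                      _["selected"] = sel,
                      _["ok"] = best.any);
}

// [[Rcpp::export]]
arma::vec cpp_boot_aic(const arma::vec& y, const arma::mat& D, int target,
                       int n_boot) {
  arma::vec out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    arma::uvec idx = boot_index(y.n_elem);
    AicBest best = aic_enumerate(y(idx), D.rows(idx), target);
    out(b) = best.any ? best.coef_target : arma::datum::nan;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Lasso: minimize (1/2n) ||y - b0 - X b||^2 + lambda * sum_j |b_j|
// by cyclic coordinate descent with covariance updates on internally
// standardized predictors (mean 0, norm sd with divisor n), warm-started
// along a decreasing lambda path. Coefficients are returned on the
// original scale; row 0 of the path matrix is the intercept.
static double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Fit path on (X, y); columns with sd < 1e-12 are left out of the penalty
// (coefficient fixed at 0). Inner loops run on raw pointers with an
// active-set strategy: iterate the nonzero set to convergence, then one
// full sweep to admit violators, repeating until the full sweep is clean.
static arma::mat lasso_path(const arma::mat& X, const arma::vec& y,
                            const arma::vec& lambda,
                            double tol = 1e-9, int max_sweeps = 1000) {
  const arma::uword n = X.n_rows, p = X.n_cols, L = lambda.n_elem;
  arma::rowvec mu = arma::mean(X, 0);
  arma::rowvec sd = arma::sqrt(arma::mean(arma::square(X.each_row() - mu), 0));
  arma::uvec active = arma::find(sd.t() > 1e-12);
  const arma::uword pa = active.n_elem;
  arma::mat Xs(n, pa);
  for (arma::uword j = 0; j < pa; ++j)
    Xs.col(j) = (X.col(active(j)) - mu(active(j))) / sd(active(j));
  double ybar = arma::mean(y);
  arma::vec yc = y - ybar;
  arma::mat G = (Xs.t() * Xs) / (double)n;     // gram, diag == 1
  arma::vec q = (Xs.t() * yc) / (double)n;
  arma::vec b(pa, arma::fill::zeros);
  // c = q - G b, maintained incrementally
  arma::vec c = q;
  const double* Gm = G.memptr();
  double* bp = b.memptr();
  double* cp = c.memptr();
  std::vector<arma::uword> inset; inset.reserve(pa);
  arma::mat path(p + 1, L, arma::fill::zeros);
  for (arma::uword l = 0; l < L; ++l) {
    double lam = lambda(l);
    for (int outer = 0; outer < max_sweeps; ++outer) {
      // full sweep over all coordinates
      double delta = 0.0;
      for (arma::uword j = 0; j < pa; ++j) {
        double bj = soft(cp[j] + bp[j], lam);
        double d = bj - bp[j];
        if (d != 0.0) {
          const double* Gj = Gm + j * pa;
          for (arma::uword k = 0; k < pa; ++k) cp[k] -= Gj[k] * d;
          bp[j] = bj;
          delta = std::max(delta, std::abs(d));
        }
      }
      if (delta < tol) break;
      // converge on the current nonzero set
      inset.clear();
      for (arma::uword j = 0; j < pa; ++j) if (bp[j] != 0.0) inset.push_back(j);
      for (int sweep = 0; sweep < max_sweeps; ++sweep) {
        double d2 = 0.0;
        for (arma::uword jj = 0; jj < inset.size(); ++jj) {
          arma::uword j = inset[jj];
          double bj = soft(cp[j] + bp[j], lam);
          double d = bj - bp[j];
          if (d != 0.0) {
            const double* Gj = Gm + j * pa;
            for (arma::uword k = 0; k < pa; ++k) cp[k] -= Gj[k] * d;
            bp[j] = bj;
            d2 = std::max(d2, std::abs(d));
          }
        }
        if (d2 < tol) break;
      }
    }
    double b0 = ybar;
    for (arma::uword j = 0; j < pa; ++j) {
      double borig = bp[j] / sd(active(j));
      path(active(j) + 1, l) = borig;
      b0 -= borig * mu(active(j));
    }
    path(0, l) = b0;
  }
  return path;
}

static arma::vec lambda_grid(const arma::mat& X, const arma::vec& y,
                             int nlambda, double min_ratio) {
  arma::rowvec mu = arma::mean(X, 0);
  arma::rowvec sd = arma::sqrt(arma::mean(arma::square(X.each_row() - mu), 0));
  double n = (double)X.n_rows, lmax = 0.0;
  arma::vec yc = y - arma::mean(y);
  for (arma::uword j = 0; j < X.n_cols; ++j) {
    if (sd(j) < 1e-12) continue;
    double c = std::abs(arma::dot((X.col(j) - mu(j)) / sd(j), yc)) / n;
    lmax = std::max(lmax, c);
  }
  if (lmax <= 0.0) lmax = 1e-3;
  return arma::exp(arma::linspace(std::log(lmax),
                                  std::log(lmax * min_ratio), nlambda));
}

// [[Rcpp::export]]
List cpp_lasso_path(const arma::vec& y, const arma::mat& X,
                    const arma::vec& lambda) {
  return List::create(_["lambda"] = lambda,
                      _["beta"] = lasso_path(X, y, lambda));
}

// 10-fold (or nfolds-fold) CV at a shared lambda grid computed on the full
// data; foldid is 1-based. Returns full-data coefficients at the CV-minimal
// lambda (ties toward the larger lambda).
static void cv_lasso_core(const arma::vec& y, const arma::mat& X,
                          const arma::ivec& foldid, int nfolds,
                          const arma::vec& lambda,
                          arma::vec& cvm, arma::vec& coef_min,
                          arma::uword& imin) {
  const arma::uword n = y.n_elem, L = lambda.n_elem;
  arma::vec sse(L, arma::fill::zeros);
  for (int f = 1; f <= nfolds; ++f) {
    arma::uvec test = arma::find(foldid == f);
    arma::uvec train = arma::find(foldid != f);
    if (test.n_elem == 0 || train.n_elem < 2) continue;
    arma::mat path = lasso_path(X.rows(train), y(train), lambda);
    arma::mat Xt(test.n_elem, X.n_cols + 1);
    Xt.col(0).ones();
    Xt.cols(1, X.n_cols) = X.rows(test);
    arma::mat pred = Xt * path;              // n_test x L
    arma::mat resid = pred.each_col() - y(test);
    sse += arma::sum(arma::square(resid), 0).t();
  }
  cvm = sse / (double)n;
  imin = cvm.index_min();
  // prefer the largest lambda achieving the minimum (lambda is decreasing)
  for (arma::uword l = 0; l < L; ++l)
    if (cvm(l) <= cvm(imin) + 1e-12) { imin = l; break; }
  arma::mat full = lasso_path(X, y, lambda);
  coef_min = full.col(imin);
}

// [[Rcpp::export]]
List cpp_lasso_cv(const arma::vec& y, const arma::mat& X,
                  const arma::ivec& foldid, int nfolds,
                  int nlambda = 100, double min_ratio = 1e-4) {
  arma::vec lambda = lambda_grid(X, y, nlambda, min_ratio);
  arma::vec cvm, coef_min;
  arma::uword imin;
  cv_lasso_core(y, X, foldid, nfolds, lambda, cvm, coef_min, imin);
  return List::create(_["lambda"] = lambda,
                      _["cvm"] = cvm,
                      _["lambda_min"] = lambda(imin),
                      _["coefficients"] = coef_min);
}

// random fold labels 1..nfolds, balanced, via R's RNG (Fisher-Yates)
static arma::ivec random_folds(arma::uword n, int nfolds) {
  arma::ivec f(n);
  for (arma::uword i = 0; i < n; ++i) f(i) = (int)(i % nfolds) + 1;
  for (arma::uword i = n - 1; i > 0; --i) {
    arma::uword j = (arma::uword)(unif_rand() * (i + 1));
    std::swap(f(i), f(j));
  }
  return f;
}

// [[Rcpp::export]]
arma::ivec cpp_random_folds(int n, int nfolds) {
  return random_folds((arma::uword)n, nfolds);
}

// [[Rcpp::export]]
arma::vec cpp_boot_lasso(const arma::vec& y, const arma::mat& X, int target,
                         int n_boot, int nfolds,
                         int nlambda = 100, double min_ratio = 1e-4) {
  arma::vec out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    arma::uvec idx = boot_index(y.n_elem);
    arma::vec yb = y(idx);
    arma::mat Xb = X.rows(idx);
    arma::ivec foldid = random_folds(yb.n_elem, nfolds);
    arma::vec lambda = lambda_grid(Xb, yb, nlambda, min_ratio);
    arma::vec cvm, coef_min;
    arma::uword imin;
    cv_lasso_core(yb, Xb, foldid, nfolds, lambda, cvm, coef_min, imin);
    out(b) = coef_min(target + 1);  // row 0 is the intercept
  }
  return out;
}
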