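#' Build a grid of data-generating-process settings
#'
#' Convenience constructor for the Monte-Carlo study: one
#' [dgp_setting()] per combination of `b` and `n_units`.
#'
#' @param b vector of confounding strengths.
#' @param n_units vector of sample sizes.
#' @param ... further arguments passed to [dgp_setting()].
#' @return A list of `dgp_setting` objects.
#' @export
dgp_grid <- function(b = c(0.5, 1.0, 1.5, 2.0, 2.5),
                     n_units = c(50, 100, 200), ...) {
  grid <- expand.grid(n_units = n_units, b = b)
  lapply(seq_len(nrow(grid)), function(i) {
    dgp_setting(n_units = grid$n_units[i], b = grid$b[i], ...)
  })
}

#' Run the Monte-Carlo comparison of causal and predictive estimators
#'
#' For each setting and trial: simulate a dataset, compute the requested
#' point estimates (IPW, OW, minimum-AIC, cross-validated lasso), and —
#' when `n_boot > 0` — a normal-approximation bootstrap confidence
#' interval per method. Cells aggregate the trial-mean estimate and the
#' fraction of intervals containing the true effect, with Monte-Carlo
#' standard errors. Each (setting, trial) pair runs on its own derived
#' seed, so any trial is reproducible in isolation.
#'
#' Trials on which an estimator fails (single treatment class in the
#' draw, or a separated propensity fit) are dropped for the affected
#' methods and counted in the cell's `n_dropped`.
#'
#' @param settings a list of [dgp_setting()]s (see [dgp_grid()]), or a
#'   single setting.
#' @param methods subset of `c("ipw", "ow", "aic", "lasso")`.
#' @param n_trials trials per setting.
#' @param n_boot bootstrap replications per trial; 0 skips interval
#'   construction (bias-only run).
#' @param seed master seed.
#' @param level confidence level for coverage.
#' @param n_folds,n_lambda,lambda_min_ratio lasso controls (see
#'   [estimate_lasso()]).
#' @return An object of class `simulation_result`: `cells` (one row per
#'   method x setting) and `trials` (the per-trial raw records the cells
#'   are derived from).
#' @examples
#' res <- run_simulation_study(dgp_setting(50, b = 0.5),
#'                             methods = c("ipw", "ow"),
#'                             n_trials = 20, seed = 1)
#' res$cells
#' @export
run_simulation_study <- function(settings,
                                 methods = c("ipw", "ow", "aic", "lasso"),
                                 n_trials, n_boot = 0, seed = 1,
                                 level = 0.95, n_folds = 10,
                                 n_lambda = 100, lambda_min_ratio = 1e-4) {
  if (inherits(settings, "dgp_setting")) settings <- list(settings)
  stopifnot(all(vapply(settings, inherits, logical(1), "dgp_setting")))
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_trials < 1) stop("n_trials must be at least 1", call. = FALSE)
  zq <- qnorm(1 - (1 - level) / 2)
  want_ps <- any(c("ipw", "ow") %in% methods)
  rows <- vector("list", length(settings) * n_trials * length(methods))
  k <- 0L
  for (s_idx in seq_along(settings)) {
    s <- settings[[s_idx]]
    for (tr in seq_len(n_trials)) {
      set.seed(derive_seed(seed, s_idx, tr))
      d <- simulate_dgp(s, seed = NULL)
      pts <- c(ipw = NA_real_, ow = NA_real_, aic = NA_real_,
               lasso = NA_real_)
      boots <- list()
      both_classes <- length(unique(d$z)) == 2L
      if (want_ps && both_classes) {
        est <- cpp_ipw_ow(d$y, d$z, d$x)
        pts["ipw"] <- est[["ipw"]]
        pts["ow"] <- est[["ow"]]
        if (n_boot > 0 && all(is.finite(est))) {
          bm <- cpp_boot_ipw_ow(d$y, d$z, d$x, n_boot)
          boots$ipw <- bm[, 1L]
          boots$ow <- bm[, 2L]
        }
      }
      if ("aic" %in% methods && both_classes) {
        D <- cbind(d$z, d$x)
        pts["aic"] <- cpp_aic_best(d$y, D, target = 0L)$coef_target
        if (n_boot > 0) boots$aic <- cpp_boot_aic(d$y, D, 0L, n_boot)
      }
      if ("lasso" %in% methods && both_classes) {
        D <- cbind(d$z, d$x)
        foldid <- cpp_random_folds(length(d$y), n_folds)
        cvfit <- cpp_lasso_cv(d$y, D, foldid, n_folds, n_lambda,
                              lambda_min_ratio)
        pts["lasso"] <- drop(cvfit$coefficients)[2L]
        if (n_boot > 0) {
          boots$lasso <- cpp_boot_lasso(d$y, D, 0L, n_boot, n_folds,
                                        n_lambda, lambda_min_ratio)
        }
      }
      for (mth in methods) {
        pt <- pts[[mth]]
        se <- ci_lo <- ci_hi <- NA_real_
        covered <- NA
        if (n_boot > 0 && is.finite(pt) && !is.null(boots[[mth]])) {
          bv <- boots[[mth]]
          ok <- is.finite(bv)
          if (sum(ok) >= n_boot / 2) {
            se <- sd(bv[ok])
            ci_lo <- pt - zq * se
            ci_hi <- pt + zq * se
            covered <- ci_lo <= s$beta_cause && s$beta_cause <= ci_hi
          }
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          setting = s_idx, b = s$b, n_units = s$n_units, trial = tr,
          method = mth, point = pt, se = se, ci_low = ci_lo,
          ci_high = ci_hi, covered = covered, stringsAsFactors = FALSE)
      }
    }
  }
  trials <- do.call(rbind, rows[seq_len(k)])
  cells <- aggregate_cells(trials, n_trials)
  structure(list(cells = cells, trials = trials,
                 parameters = list(methods = methods, n_trials = n_trials,
                                   n_boot = n_boot, seed = seed,
                                   level = level)),
            class = "simulation_result")
}

aggregate_cells <- function(trials, n_trials) {
  key <- interaction(trials$method, trials$b, trials$n_units, drop = TRUE)
  parts <- split(trials, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    ok <- is.finite(g$point)
    cov_ok <- !is.na(g$covered)
    n_eff <- sum(ok)
    mean_est <- if (n_eff) mean(g$point[ok]) else NA_real_
    mc_se <- if (n_eff > 1) sd(g$point[ok]) / sqrt(n_eff) else NA_real_
    coverage <- if (any(cov_ok)) mean(g$covered[cov_ok]) else NA_real_
    mc_se_cov <- if (any(cov_ok)) {
      sqrt(coverage * (1 - coverage) / sum(cov_ok))
    } else NA_real_
    data.frame(method = g$method[1L], b = g$b[1L], n_units = g$n_units[1L],
               n_trials = n_eff, mean_estimate = mean_est,
               mc_se_mean = mc_se, coverage = coverage,
               mc_se_coverage = mc_se_cov,
               n_dropped = nrow(g) - n_eff, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$b, out$n_units, out$method), ]
  rownames(out) <- NULL
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", nrow(x$cells), "cells;",
      x$parameters$n_trials, "trials per setting;",
      "n_boot =", x$parameters$n_boot, "\n")
  print(x$cells, digits = 4)
  invisible(x)
}

pivot_cells <- function(cells, value) {
  if (anyDuplicated(cells[, c("method", "b", "n_units")])) {
    stop("duplicate (method, b, n_units) cells", call. = FALSE)
  }
  methods <- unique(cells$method)
  keys <- unique(cells[, c("b", "n_units")])
  keys <- keys[order(keys$b, keys$n_units), , drop = FALSE]
  out <- keys
  for (mth in c("ipw", "ow", "aic", "lasso")) {
    if (!mth %in% methods) next
    out[[mth]] <- vapply(seq_len(nrow(keys)), function(i) {
      hit <- cells$method == mth & cells$b == keys$b[i] &
        cells$n_units == keys$n_units[i]
      if (any(hit)) cells[[value]][hit] else NA_real_
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Pivot simulation cells into a bias table
#'
#' One row per (b, N) with the trial-mean point estimate per method —
#' the raw mean, not mean minus truth, so an unbiased estimator of a
#' unit effect reads 1.00.
#'
#' @param cells the `cells` data frame of a [run_simulation_study()]
#'   result (or the result itself).
#' @return A data frame with columns `b`, `n_units`, and one per method.
#' @export
bias_table <- function(cells) {
  if (inherits(cells, "simulation_result")) cells <- cells$cells
  if (!nrow(cells)) stop("cells is empty", call. = FALSE)
  pivot_cells(cells, "mean_estimate")
}

#' Pivot simulation cells into a coverage table
#'
#' One row per (b, N) with the empirical 95% CI coverage per method.
#'
#' @inheritParams bias_table
#' @return A data frame with columns `b`, `n_units`, and one per method.
#' @export
coverage_table <- function(cells) {
  if (inherits(cells, "simulation_result")) cells <- cells$cells
  if (!nrow(cells)) stop("cells is empty", call. = FALSE)
  pivot_cells(cells, "coverage")
}
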