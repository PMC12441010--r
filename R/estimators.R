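new_effect_estimate <- function(method, point, se = NA_real_,
                                ci_low = NA_real_, ci_high = NA_real_,
                                meta = list()) {
  structure(
    list(method = method, point = point, se = se,
         ci_low = ci_low, ci_high = ci_high, meta = meta),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> method = %s\n  point = %.4f", x$method,
              x$point))
  if (is.finite(x$se)) cat(sprintf("  se = %.4f", x$se))
  if (is.finite(x$ci_low)) {
    cat(sprintf("  95%% CI [%.4f, %.4f]", x$ci_low, x$ci_high))
  }
  cat("\n")
  invisible(x)
}

#' Inverse-probability-weighted treatment-effect estimate
#'
#' Fits the logistic propensity model on all supplied covariates (unless
#' `scores` are given) and returns the Hajek-normalized difference of
#' inverse-probability-weighted group means:
#' `sum(z*y/e)/sum(z/e) - sum((1-z)*y/(1-e))/sum((1-z)/(1-e))`.
#'
#' @param y outcome vector.
#' @param z binary treatment vector.
#' @param x covariate matrix for the propensity model; ignored when
#'   `scores` is supplied.
#' @param scores optional fixed propensity scores in (0, 1), bypassing the
#'   logistic fit (e.g. the true scores of a simulation).
#' @return An `effect_estimate` with `method = "ipw"`.
#' @examples
#' d <- simulate_dgp(dgp_setting(200, b = 1, seed = 2))
#' estimate_ipw(d$y, d$z, d$x)$point
#' @export
estimate_ipw <- function(y, z, x = NULL, scores = NULL) {
  z <- check_binary(z)
  e <- if (is.null(scores)) fit_propensity(z, x)$scores else as.numeric(scores)
  w1 <- z / e
  w0 <- (1 - z) / (1 - e)
  point <- sum(w1 * y) / sum(w1) - sum(w0 * y) / sum(w0)
  new_effect_estimate("ipw", point)
}

#' Overlap-weighted treatment-effect estimate (ATO)
#'
#' Weights treated units by `1 - e` and controls by `e`, then takes the
#' normalized difference of weighted means. Bounded weights make this
#' robust to limited overlap, and with logistic scores the weighted
#' covariate means balance exactly between groups.
#'
#' @inheritParams estimate_ipw
#' @return An `effect_estimate` with `method = "ow"`.
#' @export
estimate_ow <- function(y, z, x = NULL, scores = NULL) {
  z <- check_binary(z)
  e <- if (is.null(scores)) fit_propensity(z, x)$scores else as.numeric(scores)
  v1 <- z * (1 - e)
  v0 <- (1 - z) * e
  point <- sum(v1 * y) / sum(v1) - sum(v0 * y) / sum(v0)
  new_effect_estimate("ow", point)
}

#' Treatment coefficient of the minimum-AIC linear model
#'
#' Enumerates every ordinary-least-squares model over the candidate set
#' (treatment plus all covariates; the intercept is always included) —
#' `2^(1 + ncol(x))` models — and returns the treatment coefficient of the
#' model with the smallest Gaussian AIC (`-2 logLik + 2k`, `k` counting
#' intercept, slopes, and the error variance, matching `stats::AIC`).
#' When the winning model excludes the treatment the point estimate is 0
#' and the metadata records the exclusion. AIC ties resolve toward fewer
#' parameters.
#'
#' @param y outcome vector.
#' @param z binary treatment vector (a selectable candidate like any
#'   covariate).
#' @param x covariate matrix.
#' @return An `effect_estimate` with `method = "aic"`; `meta$selected` is
#'   a named logical over the candidates, `meta$aic` the winning score.
#' @export
estimate_aic_best <- function(y, z, x) {
  z <- check_binary(z)
  x <- as_matrix(x)
  D <- cbind(Z = z, x)
  cn <- colnames(D)
  if (is.null(cn)) cn <- c("Z", paste0("X", seq_len(ncol(x))))
  # drop exactly collinear duplicates so the enumeration stays full rank
  qrD <- qr(cbind(1, D))
  if (qrD$rank < ncol(D) + 1L) {
    keep <- sort(setdiff(qrD$pivot[seq_len(qrD$rank)], 1L) - 1L)
    dropped <- setdiff(seq_len(ncol(D)), keep)
    warning("dropping collinear candidate columns: ",
            paste(cn[dropped], collapse = ", "), call. = FALSE)
    if (!1L %in% keep) {
      # treatment itself collinear: its effect is not identifiable
      return(new_effect_estimate("aic", 0,
                                 meta = list(selected = setNames(
                                   rep(FALSE, length(cn)), cn),
                                   aic = NA_real_, z_excluded = TRUE)))
    }
    D <- D[, keep, drop = FALSE]
    cn <- cn[keep]
  }
  if (length(y) <= ncol(D) + 2L) {
    stop("need N > number of candidate predictors + 2", call. = FALSE)
  }
  res <- cpp_aic_best(y, D, target = 0L)
  sel <- setNames(as.logical(res$selected), cn)
  new_effect_estimate("aic", res$coef_target,
                      meta = list(selected = sel, aic = res$aic,
                                  z_excluded = !sel[["Z"]]))
}

#' Treatment coefficient of the cross-validated lasso
#'
#' Minimizes `(1/2N) * RSS + lambda * sum(|slopes|)` over the intercept
#' plus one slope per candidate (treatment penalized like the rest).
#' Predictors are standardized internally (mean 0, SD 1 with divisor N)
#' and coefficients reported on the original scale. `lambda` is chosen
#' from a log-spaced grid of `n_lambda` values between `lambda_max` (the
#' smallest penalty shrinking every slope to zero) and
#' `lambda_max * lambda_min_ratio`, minimizing the `n_folds`-fold
#' cross-validation error with a seeded random fold assignment; ties go
#' to the larger (more parsimonious) penalty.
#'
#' @param y outcome vector.
#' @param z binary treatment vector.
#' @param x covariate matrix.
#' @param n_folds number of cross-validation folds.
#' @param n_lambda,lambda_min_ratio penalty-grid resolution and span.
#' @param seed optional integer seed for the fold assignment.
#' @return An `effect_estimate` with `method = "lasso"`; `meta$lambda` is
#'   the selected penalty, `meta$coefficients` the full coefficient
#'   vector (intercept first) at that penalty.
#' @export
estimate_lasso <- function(y, z, x, n_folds = 10, n_lambda = 100,
                           lambda_min_ratio = 1e-4, seed = NULL) {
  z <- check_binary(z)
  x <- as_matrix(x)
  y <- as.numeric(y)
  D <- cbind(Z = z, x)
  if (var(y) < 1e-24) {
    warning("constant outcome: all lasso slopes are zero", call. = FALSE)
    return(new_effect_estimate("lasso", 0,
                               meta = list(lambda = NA_real_,
                                           coefficients = c(mean(y),
                                                            rep(0, ncol(D))))))
  }
  with_seed(seed, {
    foldid <- cpp_random_folds(length(y), n_folds)
    res <- cpp_lasso_cv(y, D, foldid, n_folds, n_lambda, lambda_min_ratio)
  })
  coefs <- drop(res$coefficients)
  names(coefs) <- c("(Intercept)", colnames(D))
  new_effect_estimate("lasso", unname(coefs[["Z"]]),
                      meta = list(lambda = res$lambda_min,
                                  coefficients = coefs))
}

#' Overlap-weighted outcome regression
#'
#' Weighted least squares of the outcome on the treatment plus the
#' supplied (non-confounder) covariates, with overlap weights carrying
#' the confounding adjustment. This is the case-study outcome model:
#' confounders enter through the weights, the remaining covariates enter
#' the regression directly.
#'
#' @param y outcome vector.
#' @param z binary treatment vector.
#' @param x covariate matrix entering the regression (may be `NULL` for a
#'   treatment-only model).
#' @param weights a [compute_weights()] result (overlap scheme) or a
#'   nonnegative numeric vector.
#' @return An `effect_estimate` with `method = "ow_regression"`.
#' @export
ow_weighted_regression <- function(y, z, x = NULL, weights) {
  z <- check_binary(z)
  w <- if (inherits(weights, "weight_vector")) weights$weights
       else as.numeric(weights)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  D <- if (is.null(x)) cbind("(Intercept)" = rep(1, length(y)), Z = z)
       else cbind("(Intercept)" = rep(1, length(y)), Z = z, as_matrix(x))
  fit <- lm.wfit(D, as.numeric(y), w)
  if (any(is.na(fit$coefficients))) {
    bad <- names(fit$coefficients)[is.na(fit$coefficients)]
    warning("rank-deficient weighted regression; dropped: ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  new_effect_estimate("ow_regression", unname(fit$coefficients[["Z"]]),
                      meta = list(coefficients = fit$coefficients))
}
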