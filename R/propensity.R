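#' Fit a logistic propensity-score model
#'
#' Maximum-likelihood logistic regression of the binary treatment on the
#' covariates, with an intercept, solved by iteratively reweighted least
#' squares (Newton) to a relative log-likelihood tolerance of 1e-8.
#' Complete separation is detected (diverging coefficients or failure to
#' converge) and raised as an error rather than returning degenerate 0/1
#' scores.
#'
#' @param z binary treatment vector (0/1, both classes present).
#' @param x covariate matrix or data frame, no missing values.
#' @param tol,maxit IRLS convergence tolerance and iteration cap.
#' @return An object of class `propensity_fit`: named `coefficients`
#'   (intercept first), fitted `scores` strictly inside (0, 1),
#'   `converged`, and `covariate_names`.
#' @examples
#' d <- simulate_dgp(dgp_setting(200, b = 1, seed = 1))
#' fit <- fit_propensity(d$z, d$x)
#' range(fit$scores)
#' @export
fit_propensity <- function(z, x, tol = 1e-8, maxit = 100) {
  z <- check_binary(z)
  x <- as_matrix(x)
  if (nrow(x) != length(z)) {
    stop("z and x must have the same number of rows", call. = FALSE)
  }
  if (anyNA(x)) stop("x must not contain missing values", call. = FALSE)
  if (length(unique(z)) < 2L) {
    stop("treatment has no variation", call. = FALSE)
  }
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("X", seq_len(ncol(x)))
  # constant columns carry no assignment information; fit without them and
  # report a zero coefficient (reduces to the intercept-only MLE when all
  # columns are constant)
  sds <- apply(x, 2L, sd)
  keep <- which(sds > 1e-12)
  D <- cbind(1, x[, keep, drop = FALSE])
  fit <- cpp_logit_fit(D, z, tol, maxit)
  if (!fit$converged) {
    # identify the direction most aligned with perfect separation
    sep <- vapply(seq_len(ncol(x)), function(j) {
      min(x[z == 1, j]) >= max(x[z == 0, j]) ||
        max(x[z == 1, j]) <= min(x[z == 0, j])
    }, logical(1))
    dir <- if (any(sep)) {
      sprintf(" (covariate %s separates the classes)",
              paste(cn[sep], collapse = ", "))
    } else ""
    stop("logistic propensity model did not converge; complete or ",
         "quasi-complete separation suspected", dir, call. = FALSE)
  }
  scores <- pmin(pmax(drop(fit$fitted), 1e-10), 1 - 1e-10)
  coefs <- setNames(numeric(ncol(x) + 1L), c("(Intercept)", cn))
  coefs[c(1L, keep + 1L)] <- drop(fit$coefficients)
  structure(
    list(coefficients = coefs, scores = scores, converged = TRUE,
         covariate_names = cn),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit>", length(x$scores), "units;",
      "score range", sprintf("[%.4f, %.4f]", min(x$scores), max(x$scores)),
      "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Form propensity-score weights
#'
#' `ipw` gives inverse-probability-of-treatment weights
#' `z/e + (1 - z)/(1 - e)` (targets the ATE); `overlap` gives
#' `z (1 - e) + (1 - z) e` (targets the ATO), which is bounded in (0, 1)
#' and immune to extreme scores.
#'
#' @param fit a [fit_propensity()] result, or a numeric vector of scores
#'   in (0, 1).
#' @param z binary treatment vector.
#' @param scheme `"ipw"` or `"overlap"`.
#' @return An object of class `weight_vector`: `weights` and `scheme`.
#' @examples
#' compute_weights(rep(0.5, 4), c(1, 1, 0, 0), "ipw")$weights
#' @export
compute_weights <- function(fit, z, scheme = c("ipw", "overlap")) {
  scheme <- match.arg(scheme)
  z <- check_binary(z)
  e <- if (inherits(fit, "propensity_fit")) fit$scores else as.numeric(fit)
  if (length(e) != length(z)) {
    stop("scores and z must have the same length", call. = FALSE)
  }
  if (any(e <= 0 | e >= 1)) {
    stop("propensity scores must lie strictly in (0, 1)", call. = FALSE)
  }
  w <- switch(scheme,
              ipw = z / e + (1 - z) / (1 - e),
              overlap = z * (1 - e) + (1 - z) * e)
  structure(list(weights = w, scheme = scheme), class = "weight_vector")
}

#' Standardized mean difference of one covariate between treatment groups
#'
#' Absolute difference of (optionally weighted) group means divided by the
#' pooled standard deviation `sqrt((s1^2 + s0^2)/2)`. Group variances use
#' the frequency-weight convention (sample variance with denominator
#' `sum(w) - 1`), which reduces to the ordinary sample variance when
#' weights are omitted.
#'
#' @param xcol numeric covariate vector.
#' @param z binary treatment vector.
#' @param weights optional [compute_weights()] result or nonnegative
#'   numeric vector.
#' @return Nonnegative scalar SMD.
#' @examples
#' standardized_mean_difference(c(1, 3, 0, 2), c(1, 1, 0, 0))
#' @export
standardized_mean_difference <- function(xcol, z, weights = NULL) {
  z <- check_binary(z)
  x <- as.numeric(xcol)
  w <- if (is.null(weights)) {
    rep(1, length(x))
  } else if (inherits(weights, "weight_vector")) {
    weights$weights
  } else {
    as.numeric(weights)
  }
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  grp <- function(g) {
    wi <- w[z == g]; xi <- x[z == g]
    sw <- sum(wi)
    if (sw <= 0) stop("group ", g, " has zero total weight", call. = FALSE)
    m <- sum(wi * xi) / sw
    v <- sum(wi * (xi - m)^2) / max(sw - 1, .Machine$double.eps)
    c(m = m, v = v)
  }
  g1 <- grp(1); g0 <- grp(0)
  pooled <- sqrt((g1["v"] + g0["v"]) / 2)
  if (pooled < 1e-12) {
    stop("degenerate covariate: zero pooled variance", call. = FALSE)
  }
  unname(abs(g1["m"] - g0["m"]) / pooled)
}

#' Covariate balance before and after weighting
#'
#' One row per covariate with the unweighted and weighted standardized
#' mean differences, the tabular analogue of a balance (Love) plot with
#' reference lines at 0 and 0.2.
#'
#' @param x covariate matrix or data frame.
#' @param z binary treatment vector.
#' @param weights a [compute_weights()] result or numeric weights.
#' @return A data frame of class `balance_report` with columns
#'   `covariate`, `smd_unweighted`, `smd_weighted`.
#' @export
balance_report <- function(x, z, weights) {
  x <- as_matrix(x)
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("X", seq_len(ncol(x)))
  out <- data.frame(
    covariate = cn,
    smd_unweighted = vapply(seq_len(ncol(x)), function(j) {
      standardized_mean_difference(x[, j], z)
    }, numeric(1)),
    smd_weighted = vapply(seq_len(ncol(x)), function(j) {
      standardized_mean_difference(x[, j], z, weights)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("balance_report", "data.frame")
  out
}
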