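#' Bootstrap standard error and confidence interval for an estimator
#'
#' Resamples rows with replacement, applies `estimator` to each resample,
#' and forms a normal-approximation interval `point +/- z * SE` around the
#' full-data estimate, where SE is the standard deviation of the bootstrap
#' estimates. Resamples on which the estimator fails (e.g. a single
#' treatment class was drawn) are redrawn; the redraw count is recorded in
#' the metadata.
#'
#' @param data a data frame, matrix, or list of equal-row components,
#'   resampled jointly by rows.
#' @param estimator function taking the resampled data and returning a
#'   scalar point estimate, or an `effect_estimate` whose `point` is used.
#' @param n_boot number of bootstrap replications (at least 2).
#' @param seed optional integer seed.
#' @param level confidence level.
#' @param type `"normal"` (default) or `"percentile"` interval.
#' @param max_redraw per-replicate cap on redraws before the replicate is
#'   declared failed.
#' @return An `effect_estimate` with the estimator's point, bootstrap
#'   `se`, interval bounds, and `meta` holding `n_boot`, `n_redraws`, and
#'   the bootstrap draws.
#' @examples
#' d <- data.frame(x = rnorm(30))
#' bootstrap_ci(d, function(dd) mean(dd$x), n_boot = 500, seed = 1)
#' @export
bootstrap_ci <- function(data, estimator, n_boot = 1000, seed = NULL,
                         level = 0.95, type = c("normal", "percentile"),
                         max_redraw = 100) {
  type <- match.arg(type)
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  eval_est <- function(d) {
    r <- estimator(d)
    if (inherits(r, "effect_estimate")) r <- r$point
    as.numeric(r)[1]
  }
  point <- eval_est(data)
  n <- n_rows(data)
  with_seed(seed, {
    draws <- rep(NA_real_, n_boot)
    n_redraws <- 0L
    n_failed <- 0L
    for (b in seq_len(n_boot)) {
      for (r in seq_len(max_redraw)) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(eval_est(resample_rows(data, idx)),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        n_redraws <- n_redraws + 1L
      }
      if (!is.finite(val)) n_failed <- n_failed + 1L else draws[b] <- val
    }
    if (n_failed > n_boot / 2) {
      stop(sprintf("estimator failed on %d of %d bootstrap resamples",
                   n_failed, n_boot), call. = FALSE)
    }
    se <- sd(draws, na.rm = TRUE)
    if (!is.finite(se)) se <- 0
    zq <- qnorm(1 - (1 - level) / 2)
    if (type == "normal") {
      ci <- c(point - zq * se, point + zq * se)
    } else {
      ci <- unname(quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                            na.rm = TRUE))
    }
    new_effect_estimate("bootstrap", point, se, ci[1], ci[2],
                        meta = list(n_boot = n_boot, n_redraws = n_redraws,
                                    n_failed = n_failed, level = level,
                                    type = type, draws = draws))
  })
}

# ---------------------------------------------------------------------------
# EM for the multivariate normal with missing values.
# Returns MLE mean/covariance (divisor n), the observed-data log-likelihood
# trace, and convergence information. Rows with no observed cells are
# dropped. `ridge` stabilizes near-singular observed-block solves.
em_mvnorm <- function(Y, tol = 1e-7, maxit = 500, ridge = 1e-8) {
  Y <- as_matrix(Y)
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  if (n < 2L || p < 1L) stop("need at least 2 rows and 1 column",
                             call. = FALSE)
  if (any(colSums(!is.na(Y)) == 0)) {
    stop("a column is entirely missing", call. = FALSE)
  }
  obs <- !is.na(Y)
  pat_key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat_key)
  mu <- colMeans(Y, na.rm = TRUE)
  Sigma <- diag(apply(Y, 2L, var, na.rm = TRUE), p)
  diag(Sigma)[!is.finite(diag(Sigma)) | diag(Sigma) <= 0] <- 1
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  ridge_used <- 0
  safe_solve <- function(A, B) {
    r <- tryCatch(solve(A, B), error = function(e) NULL)
    if (is.null(r)) {
      ridge_used <<- max(ridge_used, ridge)
      r <- solve(A + diag(ridge, nrow(A)), B)
    }
    r
  }
  for (iter in seq_len(maxit)) {
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    ll <- 0
    for (g in groups) {
      o <- which(obs[g[1L], ])
      m <- setdiff(seq_len(p), o)
      Yo <- Y[g, o, drop = FALSE]
      ng <- length(g)
      Soo <- Sigma[o, o, drop = FALSE]
      cho <- tryCatch(chol(Soo), error = function(e) NULL)
      if (is.null(cho)) {
        ridge_used <- max(ridge_used, ridge)
        Soo <- Soo + diag(ridge, length(o))
        cho <- chol(Soo)
      }
      dev <- sweep(Yo, 2L, mu[o])
      # observed-data log-likelihood contribution
      qf <- rowSums((dev %*% chol2inv(cho)) * dev)
      ll <- ll - 0.5 * sum(qf) -
        ng * (0.5 * length(o) * log(2 * pi) + sum(log(diag(cho))))
      if (length(m) == 0L) {
        S1[o] <- S1[o] + colSums(Yo)
        S2[o, o] <- S2[o, o] + crossprod(Yo)
      } else {
        A <- Sigma[m, o, drop = FALSE] %*% chol2inv(cho)
        Em <- matrix(mu[m], ng, length(m), byrow = TRUE) + dev %*% t(A)
        Cmm <- Sigma[m, m, drop = FALSE] - A %*% Sigma[o, m, drop = FALSE]
        Yhat <- matrix(0, ng, p)
        Yhat[, o] <- Yo
        Yhat[, m] <- Em
        S1 <- S1 + colSums(Yhat)
        S2 <- S2 + crossprod(Yhat)
        S2[m, m] <- S2[m, m] + ng * Cmm
      }
    }
    mu_new <- S1 / n
    Sigma_new <- S2 / n - tcrossprod(mu_new)
    Sigma_new <- (Sigma_new + t(Sigma_new)) / 2
    mu <- mu_new
    Sigma <- Sigma_new
    if (is.finite(ll_old) &&
        abs(ll - ll_old) / (abs(ll) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll, iterations = iter,
       converged = converged, ridge = ridge_used,
       patterns = lapply(groups, function(g) {
         list(rows = g, observed = which(obs[g[1L], ]))
       }))
}

#' Little's test of missing completely at random (MCAR)
#'
#' Estimates the mean and covariance of the numeric columns by EM under
#' multivariate normality, then compares each missingness pattern's
#' observed-column means against the EM estimates:
#' `d2_j = n_j * (ybar_j - mu_j)' Sigma_j^{-1} (ybar_j - mu_j)` restricted
#' to the pattern's observed columns. The statistic is the sum of the
#' `d2_j`, chi-square with `sum(p_j) - p` degrees of freedom under MCAR.
#' With no missing cells the statistic is 0 on 0 degrees of freedom and
#' the p-value is defined as 1.
#'
#' @param data data frame or matrix of numeric columns (may contain
#'   `NA`), or a [field_dataset()] whose numeric role columns are used.
#' @param tol,maxit EM convergence tolerance and iteration cap.
#' @return An object of class `mcar_test`: `statistic`, `df`, `p.value`,
#'   `n_patterns`, and the EM fit (`em`).
#' @examples
#' fd <- generate_field_like(n_parks = 30, missing_rate = 0.1, seed = 3)
#' little_mcar_test(fd)
#' @export
little_mcar_test <- function(data, tol = 1e-7, maxit = 500) {
  if (inherits(data, "field_dataset")) {
    data <- data$data[, numeric_role_columns(data), drop = FALSE]
  }
  Y <- as_matrix(data)
  if (ncol(Y) < 2L) stop("need at least 2 numeric columns", call. = FALSE)
  # rows with no observed cells carry no information about the mechanism
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  p <- ncol(Y)
  if (!anyNA(Y)) {
    out <- list(statistic = 0, df = 0L, p.value = 1, n_patterns = 1L,
                em = NULL)
    class(out) <- "mcar_test"
    return(out)
  }
  em <- em_mvnorm(Y, tol = tol, maxit = maxit)
  stat <- 0
  sum_pj <- 0L
  for (pat in em$patterns) {
    o <- pat$observed
    nj <- length(pat$rows)
    ybar <- colMeans(Y[pat$rows, o, drop = FALSE])
    dev <- ybar - em$mu[o]
    Soo <- em$Sigma[o, o, drop = FALSE]
    inv <- tryCatch(solve(Soo), error = function(e) {
      solve(Soo + diag(1e-8, length(o)))
    })
    stat <- stat + nj * drop(t(dev) %*% inv %*% dev)
    sum_pj <- sum_pj + length(o)
  }
  df <- sum_pj - p
  pval <- if (df <= 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  out <- list(statistic = stat, df = as.integer(df), p.value = pval,
              n_patterns = length(em$patterns), em = em)
  class(out) <- "mcar_test"
  out
}

#' @export
print.mcar_test <- function(x, ...) {
  cat(sprintf(
    "Little's MCAR test: chi2 = %.3f, df = %d, p = %.4g (%d patterns)\n",
    x$statistic, x$df, x$p.value, x$n_patterns))
  invisible(x)
}

#' Multiple imputation by EM with bootstrapping
#'
#' Produces `m` completed copies of the data. For each copy the rows are
#' resampled with replacement, EM under multivariate normality estimates
#' a mean and covariance from the resample (propagating estimation
#' uncertainty), and every missing cell of the *original* rows is filled
#' with a draw from its conditional normal distribution given the row's
#' observed cells. Observed cells are never altered.
#'
#' @param data data frame or matrix of numeric columns with `NA`s, or a
#'   [field_dataset()] (its numeric role columns are imputed; treatment
#'   and park id pass through untouched).
#' @param m number of imputations.
#' @param seed optional integer seed; copy `i` uses a substream derived
#'   from it, so individual copies are reproducible.
#' @param tol,maxit EM controls.
#' @return An object of class `imputation_set`: `imputations` (list of
#'   `m` completed objects of the same class as the input) and
#'   `provenance` (seed, per-copy EM iterations and convergence flags).
#' @examples
#' fd <- generate_field_like(n_parks = 20, missing_rate = 0.1, seed = 4)
#' imp <- multiple_impute(fd, m = 3, seed = 9)
#' length(imp$imputations)
#' @export
multiple_impute <- function(data, m, seed = NULL, tol = 1e-7, maxit = 500) {
  UseMethod("multiple_impute")
}

#' @export
multiple_impute.default <- function(data, m, seed = NULL, tol = 1e-7,
                                    maxit = 500) {
  Y <- as_matrix(data)
  if (any(colSums(!is.na(Y)) == 0)) {
    stop("cannot impute: a column is entirely missing", call. = FALSE)
  }
  n <- nrow(Y); p <- ncol(Y)
  miss <- is.na(Y)
  seed0 <- if (is.null(seed)) derive_seed(Sys.time(), 1) else seed
  copies <- vector("list", m)
  iters <- integer(m)
  conv <- logical(m)
  if (!anyNA(Y)) {
    for (i in seq_len(m)) copies[[i]] <- restore_frame(Y, data)
    conv[] <- TRUE
    return(structure(list(imputations = copies,
                          provenance = list(seed = seed, em_iterations = iters,
                                            converged = conv)),
                     class = "imputation_set"))
  }
  for (i in seq_len(m)) {
    set.seed(derive_seed(seed0, i))
    idx <- sample.int(n, n, replace = TRUE)
    em <- tryCatch(em_mvnorm(Y[idx, , drop = FALSE], tol = tol,
                             maxit = maxit),
                   error = function(e) NULL)
    if (is.null(em)) { conv[i] <- FALSE; next }
    iters[i] <- em$iterations
    conv[i] <- em$converged
    Yi <- Y
    for (r in which(rowSums(miss) > 0)) {
      mm <- which(miss[r, ])
      o <- which(!miss[r, ])
      if (length(o) == 0L) {
        mu_c <- em$mu[mm]
        C <- em$Sigma[mm, mm, drop = FALSE]
      } else {
        Soo <- em$Sigma[o, o, drop = FALSE]
        A <- em$Sigma[mm, o, drop = FALSE] %*%
          tryCatch(solve(Soo), error = function(e) {
            solve(Soo + diag(1e-8, length(o)))
          })
        mu_c <- em$mu[mm] + drop(A %*% (Y[r, o] - em$mu[o]))
        C <- em$Sigma[mm, mm, drop = FALSE] - A %*% em$Sigma[o, mm, drop = FALSE]
      }
      C <- (C + t(C)) / 2
      ev <- eigen(C, symmetric = TRUE)
      ev$values[ev$values < 0] <- 0
      L <- ev$vectors %*% diag(sqrt(ev$values), length(mm))
      Yi[r, mm] <- mu_c + drop(L %*% rnorm(length(mm)))
    }
    copies[[i]] <- restore_frame(Yi, data)
  }
  failed <- !conv
  if (all(failed)) stop("EM failed to converge for every imputation",
                        call. = FALSE)
  if (mean(failed) > 0.10) {
    warning(sprintf("excluding %d of %d imputations with failed EM",
                    sum(failed), m), call. = FALSE)
    copies <- copies[!failed]
  } else if (any(failed)) {
    copies <- copies[!failed]
  }
  structure(list(imputations = copies,
                 provenance = list(seed = seed, em_iterations = iters,
                                   converged = conv)),
            class = "imputation_set")
}

restore_frame <- function(Y, template) {
  if (is.data.frame(template)) {
    out <- as.data.frame(Y)
    names(out) <- names(template)
    out
  } else Y
}

#' @export
multiple_impute.field_dataset <- function(data, m, seed = NULL, tol = 1e-7,
                                          maxit = 500) {
  cols <- numeric_role_columns(data)
  imp <- multiple_impute.default(data$data[, cols, drop = FALSE], m,
                                 seed = seed, tol = tol, maxit = maxit)
  imp$imputations <- lapply(imp$imputations, function(block) {
    df <- data$data
    df[, cols] <- block
    field_dataset(df, outcomes = data$roles$outcomes,
                  treatment = data$roles$treatment,
                  confounders = data$roles$confounders,
                  covariates = data$roles$covariates,
                  park = data$roles$park)
  })
  imp
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set>", length(x$imputations), "completed copies;",
      sum(x$provenance$converged), "EM runs converged\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and standard errors:
#' `qbar = mean(points)`, within-imputation variance `W = mean(ses^2)`,
#' between-imputation variance `B = var(points)`, total variance
#' `T = W + (1 + 1/m) B`, with a normal-quantile confidence interval.
#'
#' @param points numeric vector of per-imputation estimates.
#' @param ses matching vector of nonnegative standard errors.
#' @param level confidence level.
#' @return An object of class `pooled_estimate`: `point`, `within`,
#'   `between`, `total_variance`, `se`, `ci_low`, `ci_high`, `m`.
#' @examples
#' rubin_pool(c(1, 3), c(1, 1))
#' @export
rubin_pool <- function(points, ses, level = 0.95) {
  points <- as.numeric(points)
  ses <- as.numeric(ses)
  if (length(points) != length(ses)) {
    stop("points and ses must have the same length", call. = FALSE)
  }
  if (length(points) < 1L) stop("need at least one estimate", call. = FALSE)
  if (any(ses < 0)) stop("ses must be nonnegative", call. = FALSE)
  m <- length(points)
  qbar <- mean(points)
  W <- mean(ses^2)
  if (m == 1L) {
    warning("m = 1: between-imputation variance is undefined",
            call. = FALSE)
    B <- 0
  } else {
    B <- var(points)
  }
  total <- W + (1 + 1 / m) * B
  se <- sqrt(total)
  zq <- qnorm(1 - (1 - level) / 2)
  structure(list(point = qbar, within = W, between = B,
                 total_variance = total, se = se,
                 ci_low = qbar - zq * se, ci_high = qbar + zq * se,
                 m = m, level = level),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> point = %.4f, se = %.4f, %d%% CI [%.4f, %.4f], m = %d\n",
    x$point, x$se, round(100 * x$level), x$ci_low, x$ci_high, x$m))
  invisible(x)
}
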