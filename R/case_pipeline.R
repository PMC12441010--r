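#' Configuration of the case-study analysis
#'
#' Collects the variable roles and tuning constants of the observational
#' pipeline: which columns are outcomes, treatment, confounders (enter
#' the propensity model), and further covariates (enter the weighted
#' outcome regression); the number of imputations and bootstrap
#' replications; and which estimators to run.
#'
#' @param outcomes,treatment,confounders,covariates role column names;
#'   confounders and covariates must be disjoint and exclude the
#'   treatment.
#' @param m number of multiple imputations.
#' @param n_boot bootstrap replications per imputation.
#' @param seed master seed for imputation and bootstrap substreams.
#' @param methods subset of `c("ow", "aic", "lasso")`; `"ow"` is the
#'   overlap-weighted outcome regression, the other two are the
#'   predictive comparators over treatment plus all ten covariates.
#' @param level confidence level.
#' @param standardize_outcomes standardize the outcome columns along with
#'   the covariates (the all-continuous-variables convention); set
#'   `FALSE` to keep outcomes on their original scale.
#' @return An object of class `case_study_config`.
#' @export
case_study_config <- function(outcomes = c("FID", "VED"),
                              treatment = "Feeding",
                              confounders = c("NH", "TN", "PGS", "P"),
                              covariates = c("TD", "DT", "CO", "PL", "NP",
                                             "RG"),
                              m = 1000, n_boot = 1000, seed = 1,
                              methods = c("ow", "aic", "lasso"),
                              level = 0.95,
                              standardize_outcomes = TRUE) {
  if (length(intersect(confounders, covariates))) {
    stop("confounders and covariates must be disjoint", call. = FALSE)
  }
  if (treatment %in% c(confounders, covariates)) {
    stop("treatment cannot appear among confounders or covariates",
         call. = FALSE)
  }
  methods <- match.arg(methods, c("ow", "aic", "lasso"), several.ok = TRUE)
  structure(list(outcomes = outcomes, treatment = treatment,
                 confounders = confounders, covariates = covariates,
                 m = as.integer(m), n_boot = as.integer(n_boot),
                 seed = as.integer(seed), methods = methods,
                 level = level,
                 standardize_outcomes = isTRUE(standardize_outcomes)),
            class = "case_study_config")
}

#' Standardize the continuous columns of a field dataset
#'
#' Centers and scales every continuous role column (outcomes,
#' confounders, covariates) to mean 0 and SD 1 over its observed cells,
#' using the sample-SD (denominator n - 1) convention. The binary
#' treatment and the park id are untouched. The centers and scales are
#' stored in the `"standardization"` attribute for back-mapping.
#'
#' @param fd a [field_dataset()].
#' @param include_outcomes standardize the outcome columns too (default).
#' @return The standardized `field_dataset`.
#' @export
standardize_continuous <- function(fd, include_outcomes = TRUE) {
  stopifnot(inherits(fd, "field_dataset"))
  cols <- c(if (include_outcomes) fd$roles$outcomes,
            fd$roles$confounders, fd$roles$covariates)
  centers <- scales <- setNames(numeric(length(cols)), cols)
  for (cn in cols) {
    v <- fd$data[[cn]]
    mu <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s < 1e-12) {
      stop(sprintf("zero-variance column '%s' cannot be standardized", cn),
           call. = FALSE)
    }
    fd$data[[cn]] <- (v - mu) / s
    centers[cn] <- mu
    scales[cn] <- s
  }
  attr(fd, "standardization") <- list(center = centers, scale = scales)
  fd
}

# analysis of one completed (no-missing) dataset; returns per
# (outcome, method) point estimates with bootstrap SEs, plus the balance
# report of the confounders under overlap weights
analyze_complete <- function(df, config, seed) {
  z <- df[[config$treatment]]
  conf <- as_matrix(df[, config$confounders, drop = FALSE])
  covs <- as_matrix(df[, config$covariates, drop = FALSE])
  all_preds <- as_matrix(df[, c(config$confounders, config$covariates),
                            drop = FALSE])
  fit <- fit_propensity(z, conf)
  w_ov <- compute_weights(fit, z, "overlap")
  bal <- balance_report(conf, z, w_ov)
  rows <- list()
  for (oc in config$outcomes) {
    y <- df[[oc]]
    for (mth in config$methods) {
      est_fun <- switch(
        mth,
        ow = function(d) {
          zz <- d[[config$treatment]]
          ff <- fit_propensity(zz, as_matrix(d[, config$confounders,
                                                drop = FALSE]))
          ww <- compute_weights(ff, zz, "overlap")
          ow_weighted_regression(d[[oc]], zz,
                                 as_matrix(d[, config$covariates,
                                             drop = FALSE]), ww)$point
        },
        aic = function(d) {
          estimate_aic_best(d[[oc]], d[[config$treatment]],
                            as_matrix(d[, c(config$confounders,
                                            config$covariates),
                                        drop = FALSE]))$point
        },
        lasso = function(d) {
          estimate_lasso(d[[oc]], d[[config$treatment]],
                         as_matrix(d[, c(config$confounders,
                                         config$covariates),
                                     drop = FALSE]))$point
        })
      bs <- bootstrap_ci(df, est_fun, n_boot = config$n_boot,
                         seed = derive_seed(seed, match(oc, config$outcomes),
                                            match(mth, config$methods)),
                         level = config$level)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, method = mth, point = bs$point, se = bs$se,
        stringsAsFactors = FALSE)
    }
  }
  list(effects = do.call(rbind, rows), balance = bal)
}

#' Run the end-to-end observational case-study pipeline
#'
#' Standardize the continuous columns, test the missingness mechanism
#' (Little's MCAR test, reported but not gating), multiply impute, and —
#' per completed dataset — fit the logistic propensity model on the
#' confounders, form overlap weights, check covariate balance, estimate
#' each outcome's treatment effect by overlap-weighted regression on the
#' treatment plus the non-confounder covariates (with AIC and lasso
#' comparators over all predictors when requested), attach bootstrap
#' standard errors, and finally pool each (outcome, method) pair across
#' imputations by Rubin's rules.
#'
#' With no missing cells all imputations are identical, so the analysis
#' is computed once and replicated before pooling (between-imputation
#' variance exactly 0).
#'
#' @param fd a [field_dataset()].
#' @param config a [case_study_config()].
#' @return An object of class `case_study_result`: `effects` (one row
#'   per outcome x method with pooled point, se, CI), `balance` (mean
#'   pre/post-weighting SMD per confounder across imputations), `mcar`
#'   (the [little_mcar_test()] result), and `provenance`.
#' @examples
#' fd <- generate_field_like(n_parks = 30, missing_rate = 0, seed = 5)
#' cfg <- case_study_config(m = 2, n_boot = 50, methods = "ow")
#' run_case_study(fd, cfg)$effects
#' @export
run_case_study <- function(fd, config = case_study_config()) {
  stopifnot(inherits(fd, "field_dataset"),
            inherits(config, "case_study_config"))
  need <- c(config$outcomes, config$treatment, config$confounders,
            config$covariates)
  absent <- setdiff(need, names(fd$data))
  if (length(absent)) {
    stop("columns required by the config are absent: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  stage <- "standardization"
  result <- tryCatch({
    fd_std <- standardize_continuous(
      fd, include_outcomes = config$standardize_outcomes)
    stage <- "MCAR test"
    mcar <- little_mcar_test(fd_std)
    stage <- "multiple imputation"
    any_missing <- any(missing_mask(fd_std))
    if (any_missing) {
      imp <- multiple_impute(fd_std, m = config$m,
                             seed = derive_seed(config$seed, 0))
      completed <- imp$imputations
    } else {
      imp <- NULL
      completed <- list(fd_std)
    }
    per_imp <- vector("list", length(completed))
    balances <- vector("list", length(completed))
    for (i in seq_along(completed)) {
      stage <- sprintf("analysis of imputation %d", i)
      a <- analyze_complete(completed[[i]]$data, config,
                            seed = derive_seed(config$seed, i))
      per_imp[[i]] <- a$effects
      balances[[i]] <- a$balance
    }
    stage <- "Rubin pooling"
    all_eff <- do.call(rbind, per_imp)
    m_eff <- if (any_missing) length(completed) else config$m
    rows <- list()
    for (oc in config$outcomes) {
      for (mth in config$methods) {
        sel <- all_eff$outcome == oc & all_eff$method == mth
        pts <- all_eff$point[sel]
        ses <- all_eff$se[sel]
        if (!any_missing) {
          # identical imputations: replicate the single analysis
          pts <- rep(pts, config$m)
          ses <- rep(ses, config$m)
        }
        pool <- if (length(pts) == 1L) {
          suppressWarnings(rubin_pool(pts, ses, level = config$level))
        } else {
          rubin_pool(pts, ses, level = config$level)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = oc, method = mth, point = pool$point, se = pool$se,
          ci_low = pool$ci_low, ci_high = pool$ci_high, m = pool$m,
          stringsAsFactors = FALSE)
      }
    }
    effects <- do.call(rbind, rows)
    bal <- balances[[1L]]
    if (length(balances) > 1L) {
      bal$smd_unweighted <- rowMeans(
        sapply(balances, function(b) b$smd_unweighted))
      bal$smd_weighted <- rowMeans(
        sapply(balances, function(b) b$smd_weighted))
    }
    structure(list(effects = effects, balance = bal, mcar = mcar,
                   config = config,
                   provenance = list(
                     m = m_eff, any_missing = any_missing,
                     imputation = if (!is.null(imp)) imp$provenance,
                     standardization = attr(fd_std, "standardization"),
                     seed = config$seed)),
              class = "case_study_result")
  }, error = function(e) {
    stop(sprintf("case-study pipeline failed during %s: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' @export
print.case_study_result <- function(x, ...) {
  cat("<case_study_result> m =", x$provenance$m, "imputations\n")
  if (!is.null(x$mcar)) {
    cat(sprintf("  MCAR test: chi2 = %.2f, df = %d, p = %.3f\n",
                x$mcar$statistic, x$mcar$df, x$mcar$p.value))
  }
  cat("  pooled effects:\n")
  print(x$effects, digits = 4)
  invisible(x)
}

#' Write case-study results to delimited files plus a JSON manifest
#'
#' Writes `effects.csv` (outcome, method, point, se, ci_low, ci_high,
#' m), `balance.csv` (per-confounder SMD before/after weighting), and
#' `manifest.json` (configuration, missingness test, provenance).
#'
#' @param result a [run_case_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "case_study_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(result$effects, file.path(dir, "effects.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(result$balance), file.path(dir, "balance.csv"),
            row.names = FALSE)
  manifest <- list(
    config = unclass(result$config),
    mcar = if (!is.null(result$mcar)) {
      list(statistic = result$mcar$statistic, df = result$mcar$df,
           p = result$mcar$p.value)
    },
    provenance = list(
      m = result$provenance$m,
      any_missing = result$provenance$any_missing,
      seed = result$provenance$seed,
      standardization = result$provenance$standardization
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
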