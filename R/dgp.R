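#' Configure the confounded data-generating process
#'
#' Defines one setting of the simulation's data-generating process: six
#' iid standard-normal covariates, a binary treatment whose assignment
#' probability depends on four of them with strength `b`, and a Gaussian
#' outcome with a homogeneous treatment effect.
#'
#' The treatment-assignment coefficient vector is the fixed sign-symmetric
#' pattern `(0, 0, b, b, -b, -b)`: X1 and X2 are pure outcome predictors,
#' X3--X6 are confounders. The assignment model uses the reversed-logit
#' link `log((1 - p)/p) = X %*% beta_prop`, i.e. `p = plogis(-X %*%
#' beta_prop)`; because the coefficient pattern is sign-symmetric this only
#' determines which covariates confound positively versus negatively.
#'
#' @param n_units sample size N per simulated dataset.
#' @param b confounding strength; scales the assignment coefficients.
#' @param beta_cause true causal effect of the treatment on the outcome.
#' @param beta_out length-6 covariate effects on the outcome.
#' @param noise_sd standard deviation of the Gaussian outcome noise.
#' @param seed optional integer seed stored with the setting and used by
#'   [simulate_dgp()] when no explicit seed is passed there.
#' @return An object of class `dgp_setting`.
#' @examples
#' s <- dgp_setting(n_units = 50, b = 1.0)
#' s$beta_prop
#' @export
dgp_setting <- function(n_units, b, beta_cause = 1.0,
                        beta_out = c(1, 0.9, 0.9, -0.25, -0.25, 0),
                        noise_sd = 1.0, seed = NULL) {
  if (length(n_units) != 1L || !is.finite(n_units) || n_units < 1) {
    stop("n_units must be a positive integer", call. = FALSE)
  }
  stop_if_not_finite(b, "b")
  stop_if_not_finite(beta_cause, "beta_cause")
  stop_if_not_finite(beta_out, "beta_out")
  if (length(beta_out) != 6L) {
    stop("beta_out must have length 6", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be a positive number", call. = FALSE)
  }
  structure(
    list(
      n_units = as.integer(n_units),
      b = as.numeric(b),
      beta_cause = as.numeric(beta_cause),
      beta_prop = c(0, 0, b, b, -b, -b),
      beta_out = as.numeric(beta_out),
      noise_sd = as.numeric(noise_sd),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "dgp_setting"
  )
}

#' @export
print.dgp_setting <- function(x, ...) {
  cat("<dgp_setting> N =", x$n_units, " b =", x$b,
      " beta_cause =", x$beta_cause, "\n")
  cat("  beta_prop:", paste(format(x$beta_prop), collapse = " "), "\n")
  cat("  beta_out: ", paste(format(x$beta_out), collapse = " "), "\n")
  invisible(x)
}

#' Simulate one dataset from the confounded data-generating process
#'
#' Draws `X[, 1:6] ~ N(0, 1)` iid, computes the true assignment
#' probability `p = plogis(-X %*% beta_prop)` (reversed-logit link, see
#' [dgp_setting()]), draws `Z ~ Bernoulli(p)`, and sets
#' `Y = Z * beta_cause + X %*% beta_out + N(0, noise_sd)`.
#'
#' @param setting a [dgp_setting()].
#' @param seed optional integer seed; defaults to the setting's own seed.
#'   `NULL` leaves the RNG stream untouched.
#' @return An object of class `sim_dataset`: list with elements `y`, `z`,
#'   `x` (N x 6 matrix), `true_ps`, and the generating `setting`.
#' @examples
#' d <- simulate_dgp(dgp_setting(100, b = 1.0, seed = 1))
#' table(d$z)
#' @export
simulate_dgp <- function(setting, seed = setting$seed) {
  stopifnot(inherits(setting, "dgp_setting"))
  with_seed(seed, {
    n <- setting$n_units
    x <- matrix(rnorm(n * 6L), nrow = n, ncol = 6L,
                dimnames = list(NULL, paste0("X", 1:6)))
    # reversed-logit link: log((1 - p)/p) = X beta_prop, so p = plogis(-X beta)
    true_ps <- plogis(-drop(x %*% setting$beta_prop))
    true_ps <- pmin(pmax(true_ps, 1e-12), 1 - 1e-12)
    z <- rbinom(n, 1L, true_ps)
    y <- z * setting$beta_cause + drop(x %*% setting$beta_out) +
      rnorm(n, 0, setting$noise_sd)
    structure(
      list(y = y, z = as.numeric(z), x = x, true_ps = true_ps,
           setting = setting),
      class = "sim_dataset"
    )
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> N =", length(x$y),
      " treated =", sum(x$z),
      " b =", x$setting$b, "\n")
  invisible(x)
}
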