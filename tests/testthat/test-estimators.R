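toy <- list(z = c(1, 1, 0, 0), y = c(2, 4, 1, 3), e = c(0.8, 0.5, 0.5, 0.2))

test_that("IPW and OW reduce to the mean difference at constant scores", {
  set.seed(41)
  y <- rnorm(40)
  z <- rep(c(1, 0), 20)
  md <- mean(y[z == 1]) - mean(y[z == 0])
  expect_equal(estimate_ipw(y, z, scores = rep(0.5, 40))$point, md)
  expect_equal(estimate_ow(y, z, scores = rep(0.5, 40))$point, md)
})

test_that("IPW and OW match the hand-computed 4-unit toys", {
  # IPW: (2.5 + 8)/(1.25 + 2) - (2 + 3.75)/(2 + 1.25) = 10.5/3.25 - 5.75/3.25
  expect_equal(estimate_ipw(toy$y, toy$z, scores = toy$e)$point,
               10.5 / 3.25 - 5.75 / 3.25)
  # OW: (0.4 + 2)/(0.2 + 0.5) - (0.5 + 0.6)/(0.5 + 0.2) = 2.4/0.7 - 1.1/0.7
  expect_equal(estimate_ow(toy$y, toy$z, scores = toy$e)$point,
               2.4 / 0.7 - 1.1 / 0.7)
})

test_that("minimum-AIC search matches brute-force enumeration", {
  for (seed in c(51, 52, 53, 54, 55)) {
    set.seed(seed)
    n <- 10
    x <- matrix(rnorm(n * 2), n, 2)
    z <- rbinom(n, 1, 0.5)
    y <- 0.5 * z + x[, 1] + rnorm(n)
    est <- estimate_aic_best(y, z, x)
    oracle <- oracle_aic_best(y, z, x)
    expect_equal(est$point, oracle$coef, tolerance = 1e-8)
    expect_equal(est$meta$aic, oracle$aic, tolerance = 1e-6)
  }
})

test_that("AIC keeps a strong treatment and beats the full model", {
  set.seed(56)
  n <- 500
  x <- matrix(rnorm(n * 6), n, 6)
  z <- rbinom(n, 1, 0.5)
  y <- z + rnorm(n)
  est <- estimate_aic_best(y, z, x)
  expect_false(est$meta$z_excluded)
  expect_equal(est$point, 1, tolerance = 0.15)
  full <- AIC(lm(y ~ z + x))
  expect_lte(est$meta$aic, full + 1e-8)
})

test_that("lasso shrinks fully at lambda_max and soft-thresholds", {
  set.seed(61)
  n <- 50
  x <- matrix(rnorm(n * 3), n, 3)
  y <- x[, 1] + rnorm(n)
  # lambda_max on internally standardized predictors, centered response
  xs <- scale(x, scale = apply(x, 2, function(v) {
    sqrt(mean((v - mean(v))^2))
  }))
  lmax <- max(abs(crossprod(xs, y - mean(y)) / n))
  path <- owcausal:::cpp_lasso_path(y, x, c(lmax * 1.0001, lmax * 0.5))
  expect_equal(unname(path$beta[-1, 1]), rep(0, 3))
  expect_true(any(path$beta[-1, 2] != 0))
  # single standardized predictor: slope = soft-threshold(x'y/n, lambda)
  xs1 <- drop(scale(x[, 1], scale = sqrt(mean((x[, 1] - mean(x[, 1]))^2))))
  rho <- sum(xs1 * (y - mean(y))) / n
  for (lam in c(0.05, 0.2, 2 * abs(rho))) {
    fit <- owcausal:::cpp_lasso_path(y, matrix(xs1), lam)
    expected <- sign(rho) * max(abs(rho) - lam, 0)
    expect_equal(unname(fit$beta[2, 1]), expected, tolerance = 1e-8)
  }
})

test_that("lasso at zero penalty matches ordinary least squares", {
  set.seed(62)
  n <- 80
  x <- matrix(rnorm(n * 4), n, 4)
  z <- rbinom(n, 1, 0.5)
  y <- z + x %*% c(1, -0.5, 0, 0.25) + rnorm(n)
  D <- cbind(z, x)
  path <- owcausal:::cpp_lasso_path(drop(y), D, c(0.5, 0))
  ols <- coef(lm(y ~ D))
  expect_equal(unname(path$beta[, 2]), unname(ols), tolerance = 1e-6)
})

test_that("constant outcome returns zero slopes with a warning", {
  expect_warning(
    est <- estimate_lasso(rep(3, 20), rep(c(0, 1), 10),
                          matrix(rnorm(40), 20, 2)),
    "constant")
  expect_equal(est$point, 0)
})

test_that("weighted regression matches hand-solved normal equations", {
  set.seed(71)
  y <- c(1.2, 0.4, 2.5, 1.1, 0.3, 1.9, 2.2, 0.8)
  z <- c(1, 0, 1, 0, 0, 1, 1, 0)
  x <- matrix(rnorm(8), 8, 1)
  w <- c(0.3, 0.7, 0.4, 0.6, 0.8, 0.2, 0.5, 0.5)
  est <- ow_weighted_regression(y, z, x, w)
  X <- cbind(1, z, x)
  expect_equal(est$point, unname(oracle_wls(y, X, w)[2]), tolerance = 1e-10)
  # unit weights reduce to OLS
  est1 <- ow_weighted_regression(y, z, x, rep(1, 8))
  expect_equal(est1$point, coef(lm(y ~ z + x))[["z"]], tolerance = 1e-10)
})

test_that("treatment-only weighted regression equals the OW estimator", {
  d <- simulate_dgp(dgp_setting(150, b = 1, seed = 72))
  fit <- fit_propensity(d$z, d$x)
  w <- compute_weights(fit, d$z, "overlap")
  reg <- ow_weighted_regression(d$y, d$z, x = NULL, weights = w)
  expect_equal(reg$point, estimate_ow(d$y, d$z, scores = fit$scores)$point,
               tolerance = 1e-10)
})

test_that("estimates are location and scale equivariant", {
  d <- simulate_dgp(dgp_setting(120, b = 1, seed = 73))
  base <- c(ipw = estimate_ipw(d$y, d$z, d$x)$point,
            ow = estimate_ow(d$y, d$z, d$x)$point,
            aic = estimate_aic_best(d$y, d$z, d$x)$point)
  shifted <- c(ipw = estimate_ipw(d$y + 7, d$z, d$x)$point,
               ow = estimate_ow(d$y + 7, d$z, d$x)$point,
               aic = estimate_aic_best(d$y + 7, d$z, d$x)$point)
  expect_equal(shifted, base, tolerance = 1e-8)
  scaled <- c(ipw = estimate_ipw(3 * d$y, d$z, d$x)$point,
              ow = estimate_ow(3 * d$y, d$z, d$x)$point,
              aic = estimate_aic_best(3 * d$y, d$z, d$x)$point)
  expect_equal(scaled, 3 * base, tolerance = 1e-8)
  # lasso checked at the OLS endpoint where the penalty vanishes
  D <- cbind(d$z, d$x)
  p0 <- owcausal:::cpp_lasso_path(d$y, D, 0)$beta[2, 1]
  p3 <- owcausal:::cpp_lasso_path(3 * d$y, D, 0)$beta[2, 1]
  expect_equal(p3, 3 * p0, tolerance = 1e-6)
})

test_that("IPW with the true scores is unbiased over repeated draws", {
  # the normalized (ratio) form carries O(1/N) finite-sample bias, so the
  # known-score unbiasedness check runs at a size where that term is
  # negligible against the Monte-Carlo error
  s <- dgp_setting(400, b = 1.0)
  pts <- vapply(1:500, function(i) {
    d <- simulate_dgp(s, seed = 8000 + i)
    estimate_ipw(d$y, d$z, scores = d$true_ps)$point
  }, numeric(1))
  mc_se <- sd(pts) / sqrt(length(pts))
  expect_lt(abs(mean(pts) - s$beta_cause), 3 * mc_se)
})

test_that("penalized regression agrees with the glmnet reference", {
  library(glmnet)
  set.seed(63)
  d <- simulate_dgp(dgp_setting(120, b = 1.0, seed = 63))
  D <- cbind(Z = d$z, d$x)
  lam <- exp(seq(log(0.6), log(0.002), length.out = 25))
  mine <- owcausal:::cpp_lasso_path(d$y, D, lam)$beta
  ref <- glmnet(D, d$y, lambda = lam, standardize = TRUE, thresh = 1e-12)
  refc <- as.matrix(rbind(ref$a0, ref$beta))
  expect_lt(max(abs(mine - refc)), 1e-5)
})
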