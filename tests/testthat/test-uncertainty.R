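test_that("bootstrap of a constant estimator collapses to the point", {
  d <- data.frame(x = rnorm(20))
  est <- bootstrap_ci(d, function(dd) 2.5, n_boot = 50, seed = 1)
  expect_equal(est$se, 0)
  expect_equal(est$ci_low, 2.5)
  expect_equal(est$ci_high, 2.5)
})

test_that("bootstrap SE of the mean matches the closed form", {
  set.seed(2)
  x <- rnorm(30, sd = 2)
  d <- data.frame(x = x)
  est <- bootstrap_ci(d, function(dd) mean(dd$x), n_boot = 1e4, seed = 3)
  n <- 30
  closed <- sd(x) * sqrt((n - 1) / n) / sqrt(n)
  expect_equal(est$se, closed, tolerance = 0.05)
  expect_equal(est$point, mean(x))
  # normal CI centered on the full-data point
  expect_equal(est$ci_high - est$point, est$point - est$ci_low,
               tolerance = 1e-10)
})

test_that("bootstrap redraws degenerate resamples and reports failure", {
  d <- data.frame(z = c(1, rep(0, 9)), y = rnorm(10))
  est <- bootstrap_ci(d, function(dd) {
    if (length(unique(dd$z)) < 2) stop("one class")
    mean(dd$y[dd$z == 1]) - mean(dd$y[dd$z == 0])
  }, n_boot = 100, seed = 4)
  expect_gt(est$meta$n_redraws, 0)
  # estimator that works on the original rows but fails on (virtually)
  # every resample: the failure-rate guard must trip
  d2 <- data.frame(y = rnorm(10))
  expect_error(
    bootstrap_ci(d2, function(dd) {
      if (anyDuplicated(dd$y)) stop("tied rows")
      mean(dd$y)
    }, n_boot = 20, seed = 5, max_redraw = 2),
    "failed on")
})

test_that("complete data yields a null MCAR statistic", {
  out <- little_mcar_test(matrix(rnorm(60), 20, 3))
  expect_equal(out$statistic, 0)
  expect_equal(out$df, 0L)
  expect_equal(out$p.value, 1)
})

test_that("MCAR test matches direct arithmetic on a monotone toy", {
  set.seed(6)
  n <- 60
  x1 <- rnorm(n)
  x2 <- 0.7 * x1 + rnorm(n, sd = 0.8)
  x2[1:20] <- NA
  Y <- cbind(x1, x2)
  # closed-form factored-likelihood MLE, independent of the EM iteration
  mle <- oracle_bivariate_monotone_mle(x1, x2)
  oracle <- oracle_little_stat(Y, mle$mu, mle$Sigma)
  out <- little_mcar_test(Y, tol = 1e-12)
  expect_equal(out$statistic, oracle$statistic, tolerance = 1e-3)
  expect_equal(out$df, as.integer(oracle$df))
  expect_equal(out$em$mu, mle$mu, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(out$em$Sigma, mle$Sigma, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("MCAR p-values are calibrated under the null", {
  # sizes chosen so missingness patterns carry real mass (mostly one-hole
  # patterns with ~25 rows each); with singleton patterns the chi-square
  # approximation is visibly conservative
  pvals <- vapply(1:500, function(i) {
    fd <- generate_field_like(n_parks = 100, obs_per_park = 10,
                              missing_rate = 0.03, seed = 9000 + i)
    little_mcar_test(fd)$p.value
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.03)
  expect_lte(mean(pvals < 0.05), 0.08)
})

test_that("imputation preserves observed cells and handles complete data", {
  fd <- generate_field_like(n_parks = 15, obs_per_park = 6,
                            missing_rate = 0.15, seed = 81)
  imp <- multiple_impute(fd, m = 5, seed = 82)
  mm <- missing_mask(fd)
  src <- as.matrix(fd$data[, colnames(mm)])
  for (copy in imp$imputations) {
    filled <- as.matrix(copy$data[, colnames(mm)])
    expect_false(anyNA(filled))
    expect_identical(filled[!mm], src[!mm])
  }
  # complete data: copies identical to the input
  fd0 <- generate_field_like(n_parks = 10, obs_per_park = 4,
                             missing_rate = 0, seed = 83)
  imp0 <- multiple_impute(fd0, m = 3, seed = 84)
  for (copy in imp0$imputations) expect_identical(copy$data, fd0$data)
})

test_that("imputations track the conditional normal structure", {
  set.seed(91)
  n <- 400
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + rnorm(n, sd = sqrt(1 - 0.64))
  holes <- runif(n) < 0.3
  Y <- cbind(x1 = x1, x2 = ifelse(holes, NA, x2))
  imp <- multiple_impute(Y, m = 50, seed = 92)
  # average imputed x2 over copies, regressed on observed x1
  imputed <- sapply(imp$imputations, function(m) m[holes, "x2"])
  slope <- coef(lm(rowMeans(imputed) ~ x1[holes]))[2]
  expect_equal(unname(slope), 0.8, tolerance = 0.1)
})

test_that("Rubin pooling reproduces the worked example and identities", {
  p <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(p$point, 2)
  expect_equal(p$within, 1)
  expect_equal(p$between, 2)
  expect_equal(p$total_variance, 4)
  expect_equal(p$se, 2)
  # B = 0 when points agree
  p2 <- rubin_pool(rep(1.5, 4), rep(0.3, 4))
  expect_equal(p2$point, 1.5)
  expect_equal(p2$se, 0.3)
  # pooled point ignores the ses
  expect_equal(rubin_pool(c(0, 1, 5), c(9, 0.1, 2))$point, 2)
  # total variance never below the within component
  expect_gte(p$total_variance, p$within)
  # spreading the points can only inflate the total variance
  t_narrow <- rubin_pool(c(1.9, 2.1), c(1, 1))$total_variance
  t_wide <- rubin_pool(c(1, 3), c(1, 1))$total_variance
  expect_gt(t_wide, t_narrow)
  expect_warning(p1 <- rubin_pool(2, 0.5), "m = 1")
  expect_equal(p1$se, 0.5)
})
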