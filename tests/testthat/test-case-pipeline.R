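test_that("standardization is exact, idempotent, and skips the treatment", {
  # three-row dataset where every continuous column is {2, 4, 6}: the
  # sample-SD convention (denominator n - 1) maps it to exactly {-1, 0, 1}
  cols <- c("FID", "VED", "NH", "TN", "PGS", "P",
            "TD", "DT", "CO", "PL", "NP", "RG")
  df <- data.frame(park_id = 1:3, Feeding = c(0, 1, 0))
  df[cols] <- rep(list(c(2, 4, 6)), length(cols))
  fd <- field_dataset(df)
  std <- standardize_continuous(fd)
  for (cn in cols) expect_equal(std$data[[cn]], c(-1, 0, 1))
  expect_identical(std$data$Feeding, df$Feeding)
  # second pass changes nothing
  std2 <- standardize_continuous(std)
  expect_equal(std2$data$FID, std$data$FID, tolerance = 1e-12)
  # observed-cell convention on generated data with holes
  fd2 <- generate_field_like(n_parks = 10, obs_per_park = 5,
                             missing_rate = 0.1, seed = 201)
  s2 <- standardize_continuous(fd2)
  expect_equal(mean(s2$data$NH, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(s2$data$NH, na.rm = TRUE), 1, tolerance = 1e-12)
  # zero-variance column named in the error
  fd2$data$CO <- 1
  expect_error(standardize_continuous(fd2), "CO")
})

test_that("field CSV round-trips losslessly with roles and missingness", {
  for (seed in 300 + 1:20) {
    fd <- generate_field_like(n_parks = 8, obs_per_park = 3,
                              missing_rate = 0.2, seed = seed)
    csv <- tempfile(fileext = ".csv")
    roles <- tempfile(fileext = ".json")
    write_field_csv(fd, csv, roles_path = roles)
    back <- read_field_csv(csv, roles)
    expect_equal(back$data, fd$data, tolerance = 1e-12)
    expect_identical(back$roles$confounders, fd$roles$confounders)
    expect_identical(missing_mask(back), missing_mask(fd))
    unlink(c(csv, roles))
  }
})

test_that("non-binary treatment coding is rejected", {
  fd <- generate_field_like(n_parks = 6, obs_per_park = 2,
                            missing_rate = 0, seed = 210)
  df <- fd$data
  df$Feeding <- ifelse(df$Feeding == 1, "yes", "no")
  csv <- tempfile(fileext = ".csv")
  write.csv(df, csv, row.names = FALSE)
  expect_error(read_field_csv(csv), "0/1")
  unlink(csv)
  df2 <- fd$data
  df2$Feeding <- df2$Feeding + 1
  expect_error(field_dataset(df2), "0/1")
})

test_that("role validation catches missing and overlapping columns", {
  fd <- generate_field_like(n_parks = 6, obs_per_park = 2,
                            missing_rate = 0, seed = 211)
  expect_error(field_dataset(fd$data[, -2]), "missing role")
  expect_error(field_dataset(fd$data, confounders = c("NH", "TD")),
               "disjoint")
  expect_error(case_study_config(confounders = c("NH", "TD")), "disjoint")
  # treatment varying within a park is flagged
  df <- fd$data
  df$Feeding[1] <- 1 - df$Feeding[1]
  expect_error(field_dataset(df), "constant within")
})

test_that("complete-data pipeline equals the direct single analysis", {
  fd <- generate_field_like(n_parks = 40, obs_per_park = 5,
                            missing_rate = 0, seed = 220)
  cfg <- case_study_config(m = 3, n_boot = 60, seed = 7, methods = "ow")
  res <- run_case_study(fd, cfg)
  expect_equal(nrow(res$effects), 2)  # FID and VED
  expect_equal(res$effects$m, c(3, 3))
  # no missingness: MCAR test is the degenerate complete-pattern case
  expect_equal(res$mcar$statistic, 0)
  # pooled point equals the deterministic direct estimate
  std <- standardize_continuous(fd)
  fit <- fit_propensity(std$data$Feeding,
                        as.matrix(std$data[, cfg$confounders]))
  w <- compute_weights(fit, std$data$Feeding, "overlap")
  direct <- ow_weighted_regression(std$data$FID, std$data$Feeding,
                                   as.matrix(std$data[, cfg$covariates]), w)
  expect_equal(res$effects$point[res$effects$outcome == "FID"],
               direct$point, tolerance = 1e-10)
  # identical imputations: pooled SE equals the single bootstrap SE (B = 0)
  expect_equal(res$effects$ci_high - res$effects$point,
               qnorm(0.975) * res$effects$se, tolerance = 1e-10)
})

test_that("pipeline balances confounders after overlap weighting", {
  fd <- generate_field_like(n_parks = 60, obs_per_park = 5,
                            missing_rate = 0, seed = 221)
  cfg <- case_study_config(m = 1, n_boot = 30, seed = 8, methods = "ow")
  res <- run_case_study(fd, cfg)
  expect_identical(res$balance$covariate, cfg$confounders)
  expect_true(all(res$balance$smd_weighted < 1e-6))
})

test_that("pipeline runs through imputation with missing data", {
  fd <- generate_field_like(n_parks = 40, obs_per_park = 5,
                            missing_rate = 0.08, seed = 222)
  cfg <- case_study_config(m = 4, n_boot = 40, seed = 9,
                           methods = c("ow", "aic"))
  res <- run_case_study(fd, cfg)
  expect_equal(nrow(res$effects), 4)  # 2 outcomes x 2 methods
  expect_true(all(is.finite(res$effects$point)))
  expect_true(all(res$effects$se >= 0))
  expect_true(all(res$effects$ci_low <= res$effects$point &
                    res$effects$point <= res$effects$ci_high))
  expect_gt(res$mcar$df, 0)
  # results directory round-trip
  dir <- tempfile()
  write_results(res, dir)
  expect_true(file.exists(file.path(dir, "effects.csv")))
  expect_true(file.exists(file.path(dir, "balance.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  eff <- read.csv(file.path(dir, "effects.csv"))
  expect_equal(eff$point, res$effects$point, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("pooled results are invariant to imputation order", {
  fd <- generate_field_like(n_parks = 30, obs_per_park = 5,
                            missing_rate = 0.1, seed = 223)
  std <- standardize_continuous(fd)
  imp <- multiple_impute(std, m = 5, seed = 10)
  pts <- vapply(imp$imputations, function(copy) {
    fit <- fit_propensity(copy$data$Feeding,
                          as.matrix(copy$data[, fd$roles$confounders]))
    w <- compute_weights(fit, copy$data$Feeding, "overlap")
    ow_weighted_regression(copy$data$FID, copy$data$Feeding,
                           as.matrix(copy$data[, fd$roles$covariates]),
                           w)$point
  }, numeric(1))
  ses <- rep(0.2, 5)
  a <- rubin_pool(pts, ses)
  b <- rubin_pool(rev(pts), rev(ses))
  expect_equal(a$point, b$point)
  expect_equal(a$se, b$se)
})
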