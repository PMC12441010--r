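# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration with lm()/AIC(),
# closed-form factored-likelihood MLEs, and hand-solved normal equations.

# All-subsets AIC by brute force over lm() fits; returns the treatment
# coefficient of the minimum-AIC model (0 if excluded) and the best AIC.
oracle_aic_best <- function(y, z, x) {
  df <- data.frame(y = y, Z = z)
  xn <- paste0("V", seq_len(ncol(x)))
  df[xn] <- as.data.frame(x)
  cand <- c("Z", xn)
  best <- Inf
  best_coef <- 0
  best_k <- Inf
  for (m in 0:(2^length(cand) - 1)) {
    vars <- cand[bitwAnd(m, 2^(seq_along(cand) - 1)) > 0]
    f <- if (length(vars)) reformulate(vars, "y") else y ~ 1
    fit <- lm(f, data = df)
    a <- AIC(fit)
    k <- length(vars)
    if (a < best - 1e-12 || (abs(a - best) <= 1e-12 && k < best_k)) {
      best <- a
      best_k <- k
      best_coef <- if ("Z" %in% vars) coef(fit)[["Z"]] else 0
    }
  }
  list(aic = best, coef = best_coef)
}

# Closed-form MLE for a bivariate normal with monotone missingness
# (x1 always observed, x2 missing on a subset): the factored-likelihood
# solution. Complete rows cc, x1-only rows give the marginal of x1.
oracle_bivariate_monotone_mle <- function(x1, x2) {
  stopifnot(!anyNA(x1))
  n <- length(x1)
  cc <- which(!is.na(x2))
  mllvar <- function(v) mean((v - mean(v))^2)
  mu1 <- mean(x1)
  s11 <- mllvar(x1)
  # regression of x2 on x1 from complete rows (MLE, divisor n_cc)
  b1 <- cov(x1[cc], x2[cc]) / var(x1[cc])
  b0 <- mean(x2[cc]) - b1 * mean(x1[cc])
  s22_1 <- mllvar(x2[cc] - b0 - b1 * x1[cc])
  mu2 <- b0 + b1 * mu1
  s12 <- b1 * s11
  s22 <- s22_1 + b1^2 * s11
  list(mu = c(mu1, mu2),
       Sigma = matrix(c(s11, s12, s12, s22), 2, 2))
}

# Little's statistic computed by direct arithmetic from supplied moments.
oracle_little_stat <- function(Y, mu, Sigma) {
  obs <- !is.na(Y)
  key <- apply(obs, 1, paste, collapse = "")
  stat <- 0
  sum_pj <- 0
  for (g in split(seq_len(nrow(Y)), key)) {
    o <- which(obs[g[1], ])
    ybar <- colMeans(Y[g, o, drop = FALSE])
    d <- ybar - mu[o]
    stat <- stat + length(g) *
      drop(t(d) %*% solve(Sigma[o, o, drop = FALSE]) %*% d)
    sum_pj <- sum_pj + length(o)
  }
  list(statistic = stat, df = sum_pj - ncol(Y))
}

# Weighted least squares through explicitly solved normal equations.
oracle_wls <- function(y, X, w) {
  solve(t(X) %*% (X * w), t(X) %*% (y * w))[, 1]
}

# log-likelihood of a logistic model at given coefficients
logit_loglik <- function(beta, z, D) {
  eta <- drop(D %*% beta)
  sum(z * eta - log1p(exp(eta)))
}
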