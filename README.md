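# owcausal

Propensity-score weighting for causal effect estimation in observational
ecology, benchmarked against predictive model selection.

Field studies rarely allow randomized assignment: whether a park has
artificial feeding, whether a site is managed, whether an exposure is
present is decided by circumstances that also shape the outcome. Naive
regression or prediction-oriented variable selection (AIC, lasso) can then
attribute confounder effects to the treatment. `owcausal` implements the
two standard weighting remedies and the machinery to quantify exactly how
wrong the predictive alternatives go:

* **Estimators.** For binary treatment `Z`, outcome `Y`, covariates `X`,
  and logistic propensity score `e_i = Pr(z_i = 1 | x_i)`:
  - IPW (ATE): weights `z/e + (1-z)/(1-e)`,
  - overlap weights (ATO): `z(1-e) + (1-z)e`,

  both returned as Hájek-normalized differences of weighted group means
  `Σ w z y / Σ w z − Σ w (1−z) y / Σ w (1−z)`. Overlap weights balance the
  weighted means of every modeled covariate exactly (to solver precision)
  — the mechanism behind post-weighting standardized mean differences
  below 0.01.
  - Predictive comparators: the treatment coefficient from the minimum-AIC
    model over all `2^(p+1)` OLS subsets (0 when the treatment is
    dropped), and from an L1-penalized regression with 10-fold
    cross-validated penalty.
* **Benchmark harness.** A confounded data-generating process
  (`X ~ N(0,1)`, reversed-logit assignment `log((1−p)/p) = Xβ_prop` with
  `β_prop = (0,0,b,b,−b,−b)`, `Y = Zβ_cause + Xβ_out + N(0,1)`) and a
  Monte-Carlo driver producing bias and bootstrap-CI coverage tables over
  a `(b, N)` grid.
* **Case-study pipeline.** Standardize → Little's MCAR test → multiple
  imputation (EM with bootstrapping, multivariate normal) → per-imputation
  propensity fit, balance report, and overlap-weighted outcome regression
  (AIC/lasso comparators optional) with bootstrap SEs → Rubin's-rules
  pooling. A synthetic generator reproduces the *shape* of the
  park-clustered squirrel escape-behavior dataset (FID/VED outcomes,
  park-level feeding treatment, four confounders, six covariates, MCAR
  holes) for testing and calibration.

See `vignettes/methods.Rmd` for the statistical details and design
decisions.

## Worked example

```r
library(owcausal)

# one confounded draw: N = 200, strong confounding
d <- simulate_dgp(dgp_setting(n_units = 200, b = 1.5, seed = 42))
fit <- fit_propensity(d$z, d$x)
w <- compute_weights(fit, d$z, "overlap")
balance_report(d$x, d$z, w)
#>   covariate smd_unweighted smd_weighted
#> 1        X1          0.127     1.06e-16
#> 2        X2          0.209     0.00e+00
#> 3        X3          0.704     1.34e-16
#> 4        X4          0.623     1.17e-16
#> 5        X5          0.853     2.87e-16
#> 6        X6          0.636     3.13e-16
```

Raw imbalance is large (SMD up to 0.85 for the confounders); after overlap
weighting every modeled covariate balances exactly. The four estimates of
the unit treatment effect on this draw:

```r
estimate_ipw(d$y, d$z, d$x)$point    # 0.848
estimate_ow(d$y, d$z, d$x)$point     # 1.168
estimate_aic_best(d$y, d$z, d$x)$point          # 1.266
estimate_lasso(d$y, d$z, d$x, seed = 1)$point   # 1.218
```

Single draws scatter around the truth (1.0); the systematic differences
appear in repetition — `run_simulation_study()` shows the weighting
estimators centered on the truth while AIC/lasso attenuate at small `N`
and strong `b`, with over-narrow intervals.

The case-study pipeline end to end on synthetic field data:

```r
fd <- generate_field_like(n_parks = 12, obs_per_park = 10,
                          missing_rate = 0.05, seed = 7)
cfg <- case_study_config(m = 50, n_boot = 200, seed = 11, methods = "ow")
run_case_study(fd, cfg)
#> <case_study_result> m = 50 imputations
#>   MCAR test: chi2 = 343.94, df = 339, p = 0.415
#>   pooled effects:
#>   outcome method   point     se  ci_low ci_high  m
#> 1     FID     ow -0.3599 0.3291 -1.0050  0.2851 50
#> 2     VED     ow -0.3686 0.2860 -0.9293  0.1920 50
```

The MCAR test does not reject (missingness was generated completely at
random), and the pooled overlap-weighted effects are negative — feeding
reduces both escape distances — though 12 parks of 10 observations leave
wide intervals. All continuous variables, outcomes included, are
standardized by default, so effects are in outcome-SD units; pass
`standardize_outcomes = FALSE` in the config to keep the outcome scale.

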