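---
title: "Propensity-score weighting versus predictive model selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propensity-score weighting versus predictive model selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owcausal)
```

# The estimation problem

`owcausal` estimates the causal effect of a binary treatment $Z$ on an
outcome $Y$ from observational data in which a set of covariates $X$
influences both. Under the potential-outcome framework the unit-level
effect is $\tau_i = y_i(z_i{=}1) - y_i(z_i{=}0)$, of which only one arm is
observed; weighting by the propensity score
$e_i = \Pr(z_i = 1 \mid x_i)$ recovers averaged effects without a full
outcome model. Two weighting estimators are provided:

* **IPW** (inverse-probability weighting, targeting the ATE): weights
  $w_i = z_i/e_i + (1-z_i)/(1-e_i)$;
* **OW** (overlap weighting, targeting the ATO): weights
  $w_i = z_i(1-e_i) + (1-z_i)e_i$.

Both are returned in Hájek (normalized) form, i.e. as a difference of
weighted group means
$\sum_i w_i z_i y_i / \sum_i w_i z_i - \sum_i w_i (1-z_i) y_i / \sum_i w_i (1-z_i)$.
The unnormalized (Horvitz–Thompson) sum is not an estimator of the mean
contrast unless the weights are rescaled, so the normalized difference is
the form every weighting package computes and the one this package
implements. Overlap weights are bounded in $(0,1)$, which makes OW robust
to limited overlap, and with a logistic score they balance the weighted
means of every covariate in the propensity model *exactly* — a finite-sample
identity, not an asymptotic one — which the test suite checks to $10^{-6}$.

The propensity model is maximum-likelihood logistic regression with an
intercept, solved by iteratively reweighted least squares to a relative
deviance tolerance of $10^{-8}$ (at most 100 iterations). Complete
separation is reported as an error rather than silently returning scores of
0/1; it is detected by non-convergence, a coefficient norm above 50, or a
near-zero deviance (a perfect fit). Fitted scores are clamped to
$[10^{-10}, 1-10^{-10}]$ so downstream weights are always finite.

# The predictive comparators

The package's benchmark question is what happens when prediction-oriented
model selection is used to answer a causal question. Two standard selectors
are implemented over the candidate set {treatment, all covariates}:

* **All-subsets AIC**: every OLS model over the $2^{p+1}$ subsets (intercept
  always included), scored by Gaussian AIC
  $n\log(2\pi\widehat\sigma^2) + n + 2k$ with $k$ counting intercept, slopes
  and the error variance — identical to `stats::AIC` on an `lm` fit. The
  treatment is an ordinary candidate: when the winning model drops it the
  recorded effect is 0. Ties resolve toward fewer parameters. The
  enumeration is compiled code; the suite pins it to a brute-force
  `lm()`/`AIC()` enumeration.
* **Cross-validated lasso**: minimize $(1/2N)\,\mathrm{RSS} +
  \lambda\sum_j |\beta_j|$ with the treatment penalized like any other slope.
  Predictors are standardized internally (divisor-$N$ SD) and coefficients
  reported on the input scale. $\lambda$ runs over 100 log-spaced values from
  $\lambda_{\max}$ (the smallest penalty that zeroes every slope) down to
  $10^{-4}\lambda_{\max}$, and the selected value minimizes 10-fold
  cross-validated error (ties to the larger penalty). Coordinate descent
  uses covariance updates with warm starts and an active-set sweep,
  converging at $10^{-9}$ on the maximum coefficient change; fixed-penalty
  solutions agree with an independent reference implementation to about
  $10^{-6}$ in the test suite.

# The simulation benchmark

The data-generating process draws $X_{1..6} \sim N(0,1)$ iid, assigns
treatment with probability $p = \mathrm{logit}^{-1}(-X\beta_{prop})$ where
$\beta_{prop} = (0, 0, b, b, -b, -b)$, and sets
$Y = Z\beta_{cause} + X\beta_{out} + \varepsilon$, $\varepsilon \sim N(0,1)$,
with $\beta_{out} = (1, 0.9, 0.9, -0.25, -0.25, 0)$ and
$\beta_{cause} = 1$ by default. Two deliberate reading choices are baked in:

* The assignment link is written in *reversed* logit form,
  $\log((1-p)/p) = X\beta_{prop}$, and is implemented literally. Because the
  coefficient pattern is sign-symmetric this only decides which covariates
  confound positively versus negatively; with the asymmetric
  $\beta_{out}$ the reversed form is the one under which omitting a strong
  confounder attenuates the estimated treatment effect downward — the
  failure mode the benchmark is built to exhibit.
* The outcome coefficient vector is specified with six entries for the six
  covariates; a trailing zero in a seven-entry rendition is dropped since
  $X$ has exactly six columns.

`run_simulation_study()` repeats, per setting: simulate, estimate with each
requested method, and (optionally) build a normal-approximation bootstrap
CI ($\hat\tau \pm z_{0.975}\,\mathrm{SD}(\hat\tau^*_b)$). Every
(setting, trial) pair derives its own RNG substream from the master seed, so
any single trial can be reproduced in isolation and results do not depend
on which other methods or settings run alongside. Cells report the
trial-mean estimate (the bias table shows raw means, so an unbiased
estimator of a unit effect reads 1.00), the empirical CI coverage, and
Monte-Carlo standard errors; per-trial records are kept so tables can be
re-derived and audited.

Coverage accounting for the selection methods follows the convention that a
degenerate interval (SE 0 because the treatment was dropped in every
bootstrap resample) covers only if it hits the truth exactly — in practice,
never. Bootstrap standard deviations include the zeros recorded when
selection drops the treatment; excluding them would understate the
selection variability that the bootstrap is supposed to capture.

Two finite-sample properties of the weighting estimators are worth knowing
when reading benchmark output, and both are exercised by the test suite:

* The Hájek form is a ratio estimator with $O(1/N)$ bias. At $N = 50$ with
  six fitted covariates this is visible (trial means a few percent below the
  truth even when the *true* scores are supplied); it vanishes by
  $N \approx 400$, where the suite runs its known-score unbiasedness check.
* IPW degrades sharply once estimated scores approach 0/1. Under strong
  confounding ($b \ge 2$) the logistic fit concentrates scores near the
  boundary and inverse weights explode; trial means can attenuate by tens of
  percent. OW, whose weights are bounded, stays within Monte-Carlo error of
  the truth across the grid — that contrast is the package's central
  methodological point. Unbiasedness invariants are therefore asserted for
  IPW at moderate confounding and for OW everywhere.

No trimming of extreme scores is applied by default, so the benchmark
reports the estimators as defined; the IPW weights themselves are available via
`compute_weights()` if a user wants to inspect or trim them.

# The observational case-study pipeline

`run_case_study()` packages the full analysis sequence used for
park-clustered wildlife escape-behavior data (flight initiation distance
FID and vertical escape distance VED as outcomes; park-level artificial
feeding as the treatment; NH, TN, PGS, P as confounders entering the
propensity model; TD, DT, CO, PL, NP, RG as outcome covariates):

1. **Standardize** every continuous column to mean 0, SD 1 over observed
   cells (sample-SD convention, denominator $n-1$). Outcomes are
   standardized too by default — the all-continuous-variables convention —
   with `standardize_outcomes = FALSE` to keep effects on the original
   scale.
2. **Little's MCAR test**, reported but never gating: EM under multivariate
   normality estimates $(\hat\mu, \hat\Sigma)$; each missingness pattern $j$
   contributes $d^2_j = n_j(\bar y_j - \hat\mu_j)^\top \hat\Sigma_j^{-1}
   (\bar y_j - \hat\mu_j)$ on its observed columns; the sum is compared to
   $\chi^2$ with $\sum_j p_j - p$ degrees of freedom. EM converges at
   $10^{-7}$ relative log-likelihood (at most 500 iterations); singular
   observed blocks are ridge-stabilized with $10^{-8}$ on the diagonal and
   the stabilization is recorded. The test is exact against a closed-form
   factored-likelihood oracle in the monotone bivariate case and calibrated
   (rejection rate near 5% under MCAR) when missingness patterns carry
   real mass; with many singleton patterns the chi-square reference is
   conservative, which users should expect on small, scattered data.
3. **Multiple imputation** by EM-with-bootstrapping: each of $m$ copies
   resamples rows, estimates $(\mu^*, \Sigma^*)$ by EM on the resample, and
   fills the original rows' missing cells from their conditional normal
   given the observed cells. Observed cells are never altered. Copies whose
   EM fails are excluded (with a warning above 10% failures).
4. **Per-imputation analysis**: logistic propensity fit on the confounders,
   overlap weights, a balance report (SMD before/after weighting), and
   weighted least squares of each outcome on treatment plus the
   non-confounder covariates; optional AIC and lasso comparators over all
   predictors. Standard errors come from bootstrapping the entire
   per-imputation procedure (resample rows, refit the score, reweight,
   refit the outcome model); resampling is independent per completed
   dataset, matching the impute-then-analyze ordering.
5. **Rubin's rules** pool each (outcome, method) pair:
   $\bar q$, $W = \overline{se^2}$, $B = \mathrm{var}(q)$,
   $T = W + (1+1/m)B$, with normal-quantile intervals (no small-sample
   degrees-of-freedom correction, switchable in principle; the pooled SE
   uses $\sqrt T$).

With no missing cells every imputation is identical, so the pipeline
analyzes once and replicates the result before pooling; the pooled SE then
equals the single-dataset bootstrap SE exactly ($B = 0$).

The SMD convention divides the absolute difference of (weighted) group
means by $\sqrt{(s_1^2 + s_0^2)/2}$ with frequency-weight variances
(denominator $\sum w - 1$); the 0.2 and 0.01 reference values usually
quoted for balance plots refer to this scale. Park-level clustering is
ignored in resampling to match the row-level models of the original
analysis; a cluster bootstrap is a possible extension, not currently wired
in.

# The synthetic field generator

`generate_field_like()` emulates the *structure* of the case-study data —
not its numbers: park-level standard-normal confounders; park-level
treatment assignment by a logistic model in those confounders;
observation-level standard-normal covariates; linear outcomes with
homogeneous treatment effects and unit noise; MCAR holes at a configurable
rate (never in the treatment or the park id). Defaults are fixed once:
12 parks (the study area's size) of 10 observations, feeding coefficients
0.8 on each confounder (moderate confounding: clearly non-random
assignment, but with overlap), confounder-to-outcome coefficients 0.5 and
covariate-to-outcome coefficients 0.3 (confounders matter more, so naive
comparisons are visibly biased), treatment effects $-1.0$ on both outcomes
(the sign and order of magnitude the case study reports), and a 5% MCAR
rate (light, as in the field data). Features of real field data it does
*not* emulate: non-normal or skewed covariates, cluster-correlated outcome
noise within parks, treatment-effect heterogeneity, and non-MCAR
missingness. Passing tests on this generator therefore certify the
pipeline's mechanics (balance, pooling identities, interval calibration
under homogeneity), not robustness to those real-data features.

# Problem sizes and numerical choices

The shipped test suite runs the benchmark at reduced scale, chosen so
Monte-Carlo error is small against the effects of interest: 2,000 trials
for bias cells (MC SE of a mean near 0.01) and 1,000 trials with 200
bootstrap replications for coverage cells (coverage MC SE near 0.01); the
full-fidelity protocol (10,000 trials, 1,000 replications) is a parameter
change, not a code change. Calibration checks use 100–500 replicates with
binomial-error bands. Other constants: logistic IRLS tolerance $10^{-8}$,
separation threshold 50 on the coefficient norm; lasso grid of 100
penalties spanning $10^4$, coordinate-descent tolerance $10^{-9}$; EM
tolerance $10^{-7}$, ridge $10^{-8}$; AIC ties toward smaller models;
lasso CV ties toward stronger penalties; bootstrap resamples with a single
treatment class are redrawn (capped, with the redraw count recorded).

# Known limitations

* IPW's finite-sample behavior under poor overlap is genuinely bad (see
  above); this package reports it rather than patching it, since the
  contrast with OW is the point.
* The imputation model is a single multivariate normal: no chained
  equations, no bounded or discrete imputation, treatment and cluster id
  excluded from the model rather than conditioned on.
* Bootstrap intervals are normal-approximation by default (percentile
  intervals are available in `bootstrap_ci()`); no BCa.
* The lasso's cross-validation randomness means its point estimate is not
  a deterministic function of the data; seeds make it reproducible, not
  unique.
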