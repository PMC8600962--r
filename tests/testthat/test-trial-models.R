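test_that("unadjusted OLS treatment effect is exactly the difference in arm means", {
  tr <- continuous_trial(y = c(1, 3, 2, 4), a = c(0, 0, 1, 1))
  expect_equal(fit_linear(tr, adjusted = FALSE)$gamma_hat, 1.0)

  # equal arm means -> gamma vanishes (to solver round-off)
  tr0 <- continuous_trial(y = c(5, 7, 5, 7), a = c(0, 0, 1, 1))
  expect_equal(fit_linear(tr0, adjusted = FALSE)$gamma_hat, 0,
               tolerance = 1e-12)

  set.seed(101)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    a <- c(0, 1, rbinom(n - 2, 1, 0.5))
    y <- rnorm(n, sd = runif(1, 0.5, 3))
    tr <- continuous_trial(y = y, a = a)
    expect_equal(fit_linear(tr, adjusted = FALSE)$gamma_hat,
                 mean(y[a == 1]) - mean(y[a == 0]))
  }
})

test_that("unadjusted OLS Wald p-value equals the pooled-variance t-test p-value", {
  set.seed(20)
  y <- round(rnorm(20, mean = 1, sd = 2), 3)   # fixed listed values
  a <- rep(c(0, 1), each = 10)
  tr <- continuous_trial(y = y, a = a)
  fit <- fit_linear(tr, adjusted = FALSE)
  tt <- t.test(y[a == 1], y[a == 0], var.equal = TRUE)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(abs(fit$wald_stat), abs(unname(tt$statistic)), tolerance = 1e-12)
})

test_that("adjusting for a prognostic score never inflates the residual variance", {
  set.seed(33)
  for (i in 1:15) {
    n <- sample(10:60, 1)
    x <- rnorm(n)
    a <- c(0, 1, rbinom(n - 2, 1, 0.5))
    y <- 1 + runif(1, -2, 2) * x + 0.3 * a + rnorm(n)
    tr <- continuous_trial(y = y, x = x, a = a)
    s_adj <- fit_linear(tr, adjusted = TRUE)$sigma_hat
    s_un <- fit_linear(tr, adjusted = FALSE)$sigma_hat
    # compare sums of squares (df-free residual comparison)
    expect_lte(s_adj^2 * (n - 3), s_un^2 * (n - 2) + 1e-10)
  }
})

test_that("degenerate designs fail loudly, not silently", {
  expect_error(continuous_trial(y = 1:4, a = c(0, 0, 0, 0)), "both arms")
  a <- c(0, 0, 1, 1, 1, 0)
  tr <- continuous_trial(y = rnorm(6), x = a, a = a)  # x collinear with a
  expect_error(fit_linear(tr, adjusted = TRUE), "singular")
  tr2 <- continuous_trial(y = rnorm(6), x = rep(2, 6), a = a)
  expect_error(fit_linear(tr2, adjusted = TRUE), "singular")
  tr3 <- continuous_trial(y = rnorm(6), a = a)
  expect_error(fit_linear(tr3, adjusted = TRUE), "no baseline score")
})

test_that("wald_pvalue matches closed forms and quadrature", {
  expect_equal(wald_pvalue(0, 1, "normal"), 1.0)
  expect_equal(wald_pvalue(1.959964, 1, "normal"), 0.05, tolerance = 1e-6)
  # t reference vs numerical integration of the t density
  p_quad <- 2 * integrate(function(u) dt(u, df = 10), 2.5, Inf)$value
  expect_equal(wald_pvalue(2.5, 1, "t", df = 10), p_quad, tolerance = 1e-6)
  expect_error(wald_pvalue(1, 0), "positive")
  expect_error(wald_pvalue(1, -2), "positive")
  expect_error(wald_pvalue(1, 1, "t"), "df")
})

test_that("AFT location estimates respect the symmetry of a symmetric sample", {
  # both arms carry log-times {-1, 0, 1}: gamma must vanish and the
  # logistic location MLE of a symmetric sample is 0
  tr <- survival_trial(time = rep(c(exp(-1), 1, exp(1)), 2),
                       event = rep(1, 6), a = rep(c(0, 1), each = 3))
  fit <- fit_aft(tr, adjusted = FALSE, dist = "loglogistic")
  expect_true(fit$converged)
  expect_equal(fit$gamma_hat, 0, tolerance = 1e-5)
  expect_equal(fit$intercept_hat, 0, tolerance = 1e-5)
})

test_that("AFT fit agrees with brute-force maximization of the censored likelihood", {
  set.seed(77)
  n <- 50
  truth <- c(alpha = 0.5, beta = 0.25, gamma = 0.3, sigma = 0.5)
  x <- rnorm(n)
  a <- rep(c(0, 1), each = n / 2)
  latent <- exp(truth["alpha"] + truth["beta"] * x + truth["gamma"] * a) *
    rexp(n)^truth["sigma"]
  cens <- quantile(latent, 0.8)                      # ~20% censored
  tr <- survival_trial(time = pmin(latent, cens),
                       event = as.numeric(latent <= cens), x = x, a = a)
  for (dist in c("weibull", "loglogistic")) {
    fit <- fit_aft(tr, adjusted = TRUE, dist = dist)
    expect_true(fit$converged)
    start <- c(truth[["alpha"]], truth[["beta"]], truth[["gamma"]],
               log(truth[["sigma"]]))
    par_or <- oracle_aft_mle(tr$time, tr$event, tr$x, tr$a, start, dist)
    expect_equal(fit$intercept_hat, par_or[1], tolerance = 5e-4)
    expect_equal(fit$beta_hat, par_or[2], tolerance = 5e-4)
    expect_equal(fit$gamma_hat, par_or[3], tolerance = 5e-4)
    expect_equal(fit$scale_hat, exp(par_or[4]), tolerance = 5e-4)
    # the reported log-likelihood is the same censored likelihood
    ll <- oracle_aft_loglik(c(fit$intercept_hat, fit$beta_hat, fit$gamma_hat,
                              log(fit$scale_hat)),
                            tr$time, tr$event, tr$x, tr$a, dist)
    expect_equal(fit$loglik, ll, tolerance = 1e-6)
  }
})

test_that("the fitted likelihood is never below its value at the truth", {
  set.seed(5)
  for (i in 1:5) {
    n <- 120
    x <- rnorm(n)
    a <- rep(c(0, 1), each = n / 2)
    latent <- exp(0.5 + 0.25 * x + 0.2 * a) * rexp(n)^0.25
    cens <- quantile(latent, 0.85)
    tr <- survival_trial(time = pmin(latent, cens),
                         event = as.numeric(latent <= cens), x = x, a = a)
    fit <- fit_aft(tr, adjusted = TRUE, dist = "weibull")
    ll_hat <- oracle_aft_loglik(c(fit$intercept_hat, fit$beta_hat,
                                  fit$gamma_hat, log(fit$scale_hat)),
                                tr$time, tr$event, tr$x, tr$a, "weibull")
    ll_truth <- oracle_aft_loglik(c(0.5, 0.25, 0.2, log(0.25)),
                                  tr$time, tr$event, tr$x, tr$a, "weibull")
    expect_gte(ll_hat, ll_truth)
  }
})

test_that("a large uncensored trial recovers the log time-ratio", {
  m <- 1.5
  cfg <- survival_dgp(censor_time = 1e9)    # effectively uncensored
  tr <- gen_survival_trial(5000, m, cfg, seed = 42)
  fit <- fit_aft(tr, adjusted = TRUE, dist = "weibull")
  expect_true(fit$converged)
  expect_lt(abs(fit$gamma_hat - log(m)), 3 * fit$se_gamma)
})

test_that("uncensored no-covariate Weibull AFT matches the profile closed form", {
  set.seed(9)
  z <- log(exp(1.2) * rexp(40)^0.6)       # 40 uncensored log-times
  # identical times in both arms: gamma is 0 and the location/scale fit
  # equals the pooled one-sample smallest-extreme-value MLE
  tr <- survival_trial(time = rep(exp(z), 2), event = rep(1, 80),
                       a = rep(c(0, 1), each = 40))
  fit <- fit_aft(tr, adjusted = FALSE, dist = "weibull")
  prof <- oracle_gumbel_mle(z)
  expect_equal(fit$gamma_hat, 0, tolerance = 1e-6)
  expect_equal(fit$intercept_hat, unname(prof["mu"]), tolerance = 1e-6)
  expect_equal(fit$scale_hat, unname(prof["sigma"]), tolerance = 1e-6)
})

test_that("AFT preconditions are enforced", {
  tr <- survival_trial(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                       a = c(0, 0, 1, 1))
  expect_error(fit_aft(tr, adjusted = FALSE), "3 observed events")
  expect_error(survival_trial(time = c(1, 2, 3, 4), event = rep(0, 4),
                              a = c(0, 0, 1, 1)), "censored")
  expect_error(survival_trial(time = c(-1, 2, 3, 4), event = rep(1, 4),
                              a = c(0, 0, 1, 1)), "positive")
})
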