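#' Fit the linear analysis model for a continuous-outcome trial
#'
#' Ordinary least squares for the two analysis models compared throughout
#' the package: the score-adjusted model
#' \deqn{Y_i = \alpha + \beta X_i + \gamma A_i + \epsilon_i}
#' and the conventional (unadjusted) two-sample model
#' \deqn{Y_i = \alpha + \gamma A_i + \epsilon_i,}
#' both equivalent to ANOVA-of-change analyses. The treatment effect
#' \eqn{\gamma} is tested with a two-sided Wald (t) test on the residual
#' degrees of freedom; for the unadjusted model this reproduces the
#' pooled-variance two-sample t-test exactly, and \eqn{\hat\gamma} is the
#' difference in arm means.
#'
#' @param trial A [continuous_trial()].
#' @param adjusted Include the baseline score `x` as a covariate?
#'
#' @return A `fit_result`: list with `gamma_hat`, `se_gamma`, `wald_stat`,
#'   `p_value`, `beta_hat` (`NA` when unadjusted), `intercept_hat`,
#'   `df_residual`, `sigma_hat` (residual SD), `converged`, `model`,
#'   `adjusted`.
#' @examples
#' tr <- continuous_trial(y = c(1, 3, 2, 4), a = c(0, 0, 1, 1))
#' fit_linear(tr, adjusted = FALSE)$gamma_hat  # 3 - 2 = 1
#' @export
fit_linear <- function(trial, adjusted = TRUE) {
  stopifnot(inherits(trial, "continuous_trial"))
  if (adjusted && is.null(trial$x))
    stop("adjusted analysis requested but the trial has no baseline score 'x'",
         call. = FALSE)
  X <- if (adjusted) cbind(1, trial$x, trial$a) else cbind(1, trial$a)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p)
    stop("singular design: arms or covariate are collinear (e.g. all subjects ",
         "in one arm, or zero-variance 'x')", call. = FALSE)
  coefs <- qr.coef(qx, trial$y)
  res <- trial$y - drop(X %*% coefs)
  df <- trial$n - p
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(xtx_inv))
  gamma_hat <- coefs[p]
  se_gamma <- se[p]
  wald <- gamma_hat / se_gamma
  structure(list(
    gamma_hat = gamma_hat,
    se_gamma = se_gamma,
    wald_stat = wald,
    p_value = wald_pvalue(gamma_hat, se_gamma, reference = "t", df = df),
    beta_hat = if (adjusted) coefs[2] else NA_real_,
    intercept_hat = coefs[1],
    scale_hat = NA_real_,
    sigma_hat = sqrt(sigma2),
    df_residual = df,
    loglik = NA_real_,
    converged = TRUE,
    model = "linear",
    adjusted = adjusted
  ), class = "fit_result")
}

#' Fit an accelerated failure time model for a survival trial
#'
#' Maximum-likelihood location-scale fit on log time with right censoring,
#' \deqn{\log T_i = \alpha + \beta X_i + \gamma A_i + \sigma \epsilon_i,}
#' where the error law is logistic (`dist = "loglogistic"`) or
#' smallest-extreme-value / Gumbel-minimum (`dist = "weibull"`). Events
#' contribute the log density of log time, censored subjects the log
#' survival; standard errors come from the inverse observed information and
#' the treatment effect is tested with a two-sided Wald test against a
#' normal reference. Covariates act multiplicatively on time, so
#' \eqn{e^\gamma} is the treatment time ratio.
#'
#' Fitting is delegated to [survival::survreg()]; a failed or non-converged
#' optimization is reported through `converged = FALSE`, never as an
#' exception, so unattended Monte-Carlo loops can count and exclude it.
#'
#' @param trial A [survival_trial()] with at least 3 observed events.
#' @param adjusted Include the baseline score `x` as a covariate?
#' @param dist Error law: `"loglogistic"` (default, as in the motivating
#'   analyses) or `"weibull"`.
#'
#' @return A `fit_result` as in [fit_linear()], with `scale_hat`
#'   (\eqn{\hat\sigma}) and `loglik` filled in and `df_residual = NA`.
#' @export
fit_aft <- function(trial, adjusted = TRUE, dist = c("loglogistic", "weibull")) {
  stopifnot(inherits(trial, "survival_trial"))
  dist <- match.arg(dist)
  if (adjusted && is.null(trial$x))
    stop("adjusted analysis requested but the trial has no baseline score 'x'",
         call. = FALSE)
  if (sum(trial$event) < 3)
    stop("at least 3 observed events are required for an AFT fit", call. = FALSE)
  dat <- data.frame(time = trial$time, event = trial$event, a = trial$a)
  form <- if (adjusted) {
    dat$x <- trial$x
    survival::Surv(time, event) ~ x + a
  } else {
    survival::Surv(time, event) ~ a
  }
  failed <- function() structure(list(
    gamma_hat = NA_real_, se_gamma = NA_real_, wald_stat = NA_real_,
    p_value = NA_real_, beta_hat = NA_real_, intercept_hat = NA_real_,
    scale_hat = NA_real_, sigma_hat = NA_real_, df_residual = NA_real_,
    loglik = NA_real_, converged = FALSE, model = paste0("aft-", dist),
    adjusted = adjusted), class = "fit_result")

  ok <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      survival::survreg(form, data = dat, dist = dist),
      error = function(e) NULL),
    warning = function(w) {
      ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit)) return(failed())
  V <- fit$var
  cf <- fit$coefficients
  k <- length(cf)             # gamma is the last regression coefficient
  if (!all(is.finite(V)) || V[k, k] <= 0 || anyNA(cf)) return(failed())
  gamma_hat <- unname(cf[k])
  se_gamma <- sqrt(V[k, k])
  wald <- gamma_hat / se_gamma
  structure(list(
    gamma_hat = gamma_hat,
    se_gamma = se_gamma,
    wald_stat = wald,
    p_value = wald_pvalue(gamma_hat, se_gamma, reference = "normal"),
    beta_hat = if (adjusted) unname(cf[2]) else NA_real_,
    intercept_hat = unname(cf[1]),
    scale_hat = fit$scale,
    sigma_hat = fit$scale,
    df_residual = NA_real_,
    loglik = fit$loglik[2],
    converged = ok,
    model = paste0("aft-", dist),
    adjusted = adjusted
  ), class = "fit_result")
}

#' Two-sided Wald p-value
#'
#' Tail probability of `|estimate / se|` under a standard normal or a t
#' reference distribution.
#'
#' @param estimate Point estimate.
#' @param se Standard error, strictly positive.
#' @param reference `"normal"` (ML asymptotics) or `"t"` (regression).
#' @param df Degrees of freedom, required for the t reference.
#' @return A probability in `[0, 1]`.
#' @examples
#' wald_pvalue(1.959964, 1, "normal")  # 0.05
#' @export
wald_pvalue <- function(estimate, se, reference = c("normal", "t"), df = NULL) {
  reference <- match.arg(reference)
  if (!is.finite(se) || se <= 0) stop("'se' must be a positive number", call. = FALSE)
  z <- abs(estimate / se)
  if (reference == "normal") {
    2 * stats::pnorm(-z)
  } else {
    if (is.null(df) || df < 1) stop("'df' is required for the t reference", call. = FALSE)
    2 * stats::pt(-z, df = df)
  }
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (%s)\n", x$model,
              if (isTRUE(x$adjusted)) "score-adjusted" else "unadjusted"))
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  gamma_hat = %.4f (se %.4f), wald = %.3f, p = %.4g\n",
              x$gamma_hat, x$se_gamma, x$wald_stat, x$p_value))
  if (isTRUE(x$adjusted)) cat(sprintf("  beta_hat  = %.4f\n", x$beta_hat))
  if (!is.na(x$scale_hat)) cat(sprintf("  scale_hat = %.4f\n", x$scale_hat))
  invisible(x)
}
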