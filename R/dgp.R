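#' Configuration of the synthetic continuous-outcome generating process
#'
#' The continuous data-generating process is
#' \deqn{Y_i = \alpha + \beta X_i + \gamma A_i + \epsilon_i,}
#' with \eqn{X_i \sim N(0, \code{x\_scale})}, \eqn{\epsilon_i \sim N(0,
#' \code{sigma\_eps}^2)} and \eqn{A_i \sim \mathrm{Bernoulli}(\code{p\_treat})}
#' independent of \eqn{X}. Defaults: \eqn{\alpha = 2}, \eqn{\beta = 4},
#' `x_scale = 0.25`, `sigma_eps = 1`, `p_treat = 0.5`.
#'
#' `x_scale_is_sd` resolves the notational ambiguity of "N(0, 0.25)": with
#' `FALSE` (default) 0.25 is the variance of \eqn{X}, the conventional
#' reading of \eqn{N(\mu, \sigma^2)}; with `TRUE` it is the standard
#' deviation. Both are exposed because the two readings change the marginal
#' outcome SD (\eqn{\sqrt 5} vs \eqn{\sqrt 2}) and therefore every
#' downstream sample-size number; see the package vignette for which
#' reading reproduces the reference sample-size curves.
#'
#' @param alpha Intercept.
#' @param beta Coefficient of the prognostic score.
#' @param x_scale Dispersion of the score's normal law.
#' @param x_scale_is_sd Interpret `x_scale` as an SD (`TRUE`) or a variance
#'   (`FALSE`, default).
#' @param sigma_eps SD of the normal error.
#' @param p_treat Randomization probability of the treated arm.
#' @return A list of class `continuous_dgp`.
#' @export
continuous_dgp <- function(alpha = 2, beta = 4, x_scale = 0.25,
                           x_scale_is_sd = FALSE, sigma_eps = 1,
                           p_treat = 0.5) {
  stopifnot(x_scale > 0, sigma_eps > 0, p_treat > 0, p_treat < 1)
  structure(list(alpha = alpha, beta = beta, x_scale = x_scale,
                 x_scale_is_sd = isTRUE(x_scale_is_sd),
                 sigma_eps = sigma_eps, p_treat = p_treat),
            class = "continuous_dgp")
}

# SD of X implied by the configured convention
x_sd_of <- function(cfg) if (cfg$x_scale_is_sd) cfg$x_scale else sqrt(cfg$x_scale)

#' Marginal outcome SD implied by a continuous DGP
#'
#' Closed form \eqn{\sqrt{\beta^2 \mathrm{Var}(X) + \sigma_\epsilon^2}}
#' (within-arm SD; the treatment effect adds nothing under the null).
#' Used by [effect_to_gamma()] to convert standardized effect sizes.
#'
#' @param cfg A [continuous_dgp()].
#' @return The marginal SD of Y.
#' @export
dgp_outcome_sd <- function(cfg) {
  stopifnot(inherits(cfg, "continuous_dgp"))
  sqrt(cfg$beta^2 * x_sd_of(cfg)^2 + cfg$sigma_eps^2)
}

#' Configuration of the synthetic survival generating process
#'
#' Latent event times follow the Weibull accelerated failure time law
#' \deqn{\log T_i = \alpha + \beta X_i + \sigma \epsilon_i,}
#' with \eqn{X_i \sim N(0, \code{x\_sd}^2)} and \eqn{\epsilon_i} following
#' the smallest-extreme-value (Gumbel-minimum) distribution, so that
#' \eqn{T_i} is Weibull with shape \eqn{1/\sigma}. Treated subjects' latent
#' event times are multiplied by the effect multiplier, then every time is
#' administratively censored at `censor_time` months (event recorded only
#' if the latent time is at most the horizon). Defaults: \eqn{\alpha = 0.5},
#' \eqn{\beta = 0.25}, `x_sd = 1`, `error_scale = 4` with
#' `scale_is_shape = TRUE`, `censor_time = 36`, `p_treat = 0.5`.
#'
#' `scale_is_shape` resolves which role the printed dispersion value plays:
#' with `TRUE` (default) `error_scale` is the Weibull shape \eqn{k} and
#' \eqn{\sigma = 1/k} (so the default is \eqn{\sigma = 1/4}); with `FALSE`
#' `error_scale` is \eqn{\sigma} itself. The default is the reading under
#' which required sample sizes land in the realistic few-hundreds range
#' (see the vignette); \eqn{\sigma = 4} puts them in the tens of thousands.
#'
#' @param alpha Intercept on the log-time scale (log months).
#' @param beta Coefficient of the prognostic score.
#' @param x_sd SD of the score.
#' @param error_scale Dispersion of the extreme-value error; interpretation
#'   set by `scale_is_shape`.
#' @param scale_is_shape Interpret `error_scale` as the Weibull shape
#'   (`TRUE`, default, \eqn{\sigma = 1/\code{error\_scale}}) or as
#'   \eqn{\sigma} directly (`FALSE`).
#' @param censor_time Administrative (end-of-study) censoring horizon in
#'   months.
#' @param p_treat Randomization probability of the treated arm.
#' @return A list of class `survival_dgp` with the resolved `sigma`.
#' @export
survival_dgp <- function(alpha = 0.5, beta = 0.25, x_sd = 1, error_scale = 4,
                         scale_is_shape = TRUE, censor_time = 36,
                         p_treat = 0.5) {
  stopifnot(error_scale > 0, x_sd > 0, censor_time > 0,
            p_treat > 0, p_treat < 1)
  sigma <- if (isTRUE(scale_is_shape)) 1 / error_scale else error_scale
  structure(list(alpha = alpha, beta = beta, x_sd = x_sd,
                 error_scale = error_scale,
                 scale_is_shape = isTRUE(scale_is_shape),
                 sigma = sigma, censor_time = censor_time, p_treat = p_treat),
            class = "survival_dgp")
}

# All synthetic randomness is driven by one standard-normal stream laid out
# subject-major (all variables of subject i before those of subject i+1), so
# that for a fixed seed the first m subjects are identical for every n >= m.
# This is what makes common-random-number comparisons across trial sizes
# meaningful in the power engine.
subject_stream <- function(n, vars, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(vars * n)
  dim(z) <- c(vars, n)
  z
}

#' Generate one synthetic continuous-outcome trial
#'
#' Draws a trial of size `n` from the process in [continuous_dgp()] with a
#' treatment effect `gamma` added to the treated arm's outcomes (on the
#' outcome scale).
#'
#' @param n Number of subjects (at least 4).
#' @param gamma Treatment effect on the outcome scale (0 for the null).
#' @param cfg A [continuous_dgp()].
#' @param seed Optional integer seed; a fixed seed reproduces the trial
#'   exactly, and for fixed seed the first `m` subjects agree across all
#'   `n >= m`.
#' @return A [continuous_trial()].
#' @export
gen_continuous_trial <- function(n, gamma, cfg = continuous_dgp(), seed = NULL) {
  stopifnot(inherits(cfg, "continuous_dgp"))
  if (n < 4) stop("'n' must be at least 4", call. = FALSE)
  z <- subject_stream(n, 3L, seed)
  x <- x_sd_of(cfg) * z[1L, ]
  a <- as.numeric(stats::pnorm(z[2L, ]) < cfg$p_treat)
  y <- cfg$alpha + cfg$beta * x + gamma * a + cfg$sigma_eps * z[3L, ]
  continuous_trial(y = y, x = x, a = a)
}

#' Generate one synthetic survival trial
#'
#' Draws latent Weibull event times from the process in [survival_dgp()],
#' multiplies the treated arm's latent event times by `effect_multiplier`
#' (the survival effect size: the AFT time ratio, \eqn{e^{\gamma}}), then
#' applies end-of-study censoring: any latent time beyond `censor_time` is
#' recorded as `(censor_time, event = 0)`. All returned times are at most
#' the horizon and the event indicator equals `latent <= censor_time`
#' exactly.
#'
#' @param n Number of subjects (at least 4).
#' @param effect_multiplier Positive time ratio (1 for the null).
#' @param cfg A [survival_dgp()].
#' @param seed Optional integer seed (same contract as
#'   [gen_continuous_trial()]).
#' @return A [survival_trial()].
#' @export
gen_survival_trial <- function(n, effect_multiplier, cfg = survival_dgp(),
                               seed = NULL) {
  stopifnot(inherits(cfg, "survival_dgp"))
  if (n < 4) stop("'n' must be at least 4", call. = FALSE)
  if (!is.finite(effect_multiplier) || effect_multiplier <= 0)
    stop("'effect_multiplier' must be positive", call. = FALSE)
  z <- subject_stream(n, 3L, seed)
  x <- cfg$x_sd * z[1L, ]
  a <- as.numeric(stats::pnorm(z[2L, ]) < cfg$p_treat)
  e_unit <- stats::qexp(stats::pnorm(z[3L, ]))    # Exp(1); log(e_unit) is Gumbel-min
  latent <- exp(cfg$alpha + cfg$beta * x) * e_unit^cfg$sigma
  latent[a == 1] <- latent[a == 1] * effect_multiplier
  event <- as.numeric(latent <= cfg$censor_time)
  time <- pmin(latent, cfg$censor_time)
  survival_trial(time = time, event = event, x = x, a = a)
}

#' Generate a synthetic observational cohort
#'
#' Fixture stand-in for the real source cohorts that the plasmode machinery
#' resamples (an MCI cohort with a continuous 2-year cognitive-change
#' outcome, or a survival cohort with a score-dependent log time and a
#' configurable censored fraction). No real data are used: the cohort is a
#' synthetic emulation with a marked correlation structure only.
#'
#' Continuous flavor: `x ~ N(0, 1)` and
#' `y = mu_y + sd_y * (strength * x + sqrt(1 - strength^2) * z)`, so the
#' population correlation of `x` and `y` is exactly `strength`; defaults
#' `mu_y = -0.17`, `sd_y = 0.49` echo a 2-year memory-change scale.
#' Survival flavor: `log(time) = log_t0 + tau * (strength * x +
#' sqrt(1 - strength^2) * z)` with `log_t0 = log(12)` months and
#' `tau = 0.8`; administrative censoring is applied at the empirical
#' `(1 - censor_frac)` quantile of the latent times, so the realized
#' censored fraction matches `censor_frac` to within 1/n.
#'
#' @param n Cohort size (at least 20).
#' @param outcome_type `"continuous"` or `"survival"`.
#' @param strength Score-outcome correlation in `[-1, 1]` (for survival, the
#'   correlation on the log-time scale).
#' @param censor_frac Target censored fraction in `[0, 1)`; survival only.
#' @param mu_y,sd_y Location and scale of the continuous outcome.
#' @param log_t0,tau Location and scale of log time (survival).
#' @param seed Optional integer seed.
#' @return A [cohort()].
#' @export
gen_synthetic_cohort <- function(n, outcome_type = c("continuous", "survival"),
                                 strength = 0.5, censor_frac = 0,
                                 mu_y = -0.17, sd_y = 0.49,
                                 log_t0 = log(12), tau = 0.8, seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (n < 20) stop("'n' must be at least 20", call. = FALSE)
  if (abs(strength) > 1) stop("'strength' must lie in [-1, 1]", call. = FALSE)
  if (censor_frac < 0 || censor_frac >= 1)
    stop("'censor_frac' must lie in [0, 1)", call. = FALSE)
  z <- subject_stream(n, 2L, seed)
  x <- z[1L, ]
  lin <- strength * x + sqrt(1 - strength^2) * z[2L, ]
  if (outcome_type == "continuous") {
    cohort(x = x, y = mu_y + sd_y * lin)
  } else {
    latent <- exp(log_t0 + tau * lin)
    if (censor_frac > 0) {
      horizon <- unname(stats::quantile(latent, 1 - censor_frac, type = 1))
      event <- as.numeric(latent <= horizon)
      cohort(x = x, time = pmin(latent, horizon), event = event)
    } else {
      cohort(x = x, time = latent, event = rep(1, n))
    }
  }
}
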