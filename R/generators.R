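#' Trial generators for the power engine
#'
#' A trial generator bundles a source of simulated trials with the metadata
#' the power engine needs: its outcome type and (for continuous outcomes)
#' the outcome SD used to convert standardized effect sizes. The `generate`
#' element is a function `(n, effect, seed)` returning one trial, where
#' `effect` is already on the model scale — an additive \eqn{\gamma} for
#' continuous outcomes, a time ratio for survival outcomes.
#'
#' @param cfg A [continuous_dgp()] or [survival_dgp()].
#' @return An object of class `trial_generator`.
#' @name trial_generators
NULL

new_trial_generator <- function(type, generate, outcome_sd = NULL, label = "") {
  structure(list(type = type, generate = generate, outcome_sd = outcome_sd,
                 label = label),
            class = "trial_generator")
}

#' @rdname trial_generators
#' @export
synthetic_continuous_generator <- function(cfg = continuous_dgp()) {
  stopifnot(inherits(cfg, "continuous_dgp"))
  new_trial_generator(
    type = "continuous",
    generate = function(n, effect, seed = NULL)
      gen_continuous_trial(n, gamma = effect, cfg = cfg, seed = seed),
    outcome_sd = dgp_outcome_sd(cfg),
    label = "synthetic-continuous")
}

#' @rdname trial_generators
#' @export
synthetic_survival_generator <- function(cfg = survival_dgp()) {
  stopifnot(inherits(cfg, "survival_dgp"))
  new_trial_generator(
    type = "survival",
    generate = function(n, effect, seed = NULL)
      gen_survival_trial(n, effect_multiplier = effect, cfg = cfg, seed = seed),
    label = "synthetic-survival")
}

#' Plasmode trial generator from an observational cohort
#'
#' Splits the cohort once (held fixed across Monte-Carlo iterations, the
#' default) and resamples arms independently each iteration via
#' [resample_trial()]. With `resplit = TRUE` a fresh random split is drawn
#' every iteration instead. For continuous cohorts the effect-size
#' conversion SD is the outcome SD of the *full* cohort, computed before
#' splitting.
#'
#' @param cohort A [cohort()].
#' @param split_seed Seed for the (fixed) source split.
#' @param admin_censor_time Optional end-of-study horizon in months
#'   (survival cohorts only); `NULL` applies no extra truncation.
#' @param resplit Re-split the cohort at every iteration? Default `FALSE`.
#' @return A `trial_generator`.
#' @export
plasmode_generator <- function(cohort, split_seed = 1L,
                               admin_censor_time = NULL, resplit = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  type <- outcome_type(cohort)
  if (!is.null(admin_censor_time) && type == "continuous")
    stop("'admin_censor_time' applies only to survival cohorts", call. = FALSE)
  fixed_split <- split_cohort(cohort, seed = split_seed)
  wrap_effect <- if (type == "continuous") effect_additive else effect_multiplicative
  gen <- function(n, effect, seed = NULL) {
    if (resplit) {
      sp <- split_cohort(cohort, seed = seed)
      # the split consumed the stream head; resampling continues it
      resample_trial(sp, n, wrap_effect(effect),
                     admin_censor_time = admin_censor_time, seed = NULL)
    } else {
      resample_trial(fixed_split, n, wrap_effect(effect),
                     admin_censor_time = admin_censor_time, seed = seed)
    }
  }
  g <- new_trial_generator(
    type = type, generate = gen,
    outcome_sd = if (type == "continuous") stats::sd(cohort$y),
    label = paste0("plasmode-", type))
  g$split <- fixed_split
  g
}

#' @export
print.trial_generator <- function(x, ...) {
  cat(sprintf("<trial_generator> %s", x$label))
  if (!is.null(x$outcome_sd)) cat(sprintf(" (outcome SD %.4f)", x$outcome_sd))
  cat("\n")
  invisible(x)
}
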