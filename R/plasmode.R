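#' Split a cohort into treated-source and control-source halves
#'
#' First step of a plasmode simulation: the observational cohort is randomly
#' partitioned into two (near-)equal halves, one serving as the source of
#' the simulated control arm and the other as the source of the simulated
#' treated arm. For odd cohorts the control source receives the extra
#' subject (sizes `ceiling(n/2)` and `floor(n/2)`); the partition is
#' deterministic for a fixed seed.
#'
#' @param cohort A [cohort()] of at least 8 subjects.
#' @param seed Optional integer seed.
#' @return An object of class `plasmode_split`: list with cohort subsets
#'   `source_control` and `source_treated`.
#' @export
split_cohort <- function(cohort, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort)
  if (n < 8) stop("the cohort must contain at least 8 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  n_ctrl <- ceiling(n / 2)
  structure(list(
    source_control = cohort[sort(perm[seq_len(n_ctrl)]), , drop = FALSE],
    source_treated = cohort[sort(perm[(n_ctrl + 1):n]), , drop = FALSE]
  ), class = "plasmode_split")
}

#' @export
print.plasmode_split <- function(x, ...) {
  cat(sprintf("<plasmode_split> control source: %d, treated source: %d (%s outcome)\n",
              nrow(x$source_control), nrow(x$source_treated),
              outcome_type(x$source_control)))
  invisible(x)
}

#' Treatment-effect specifications for plasmode resampling
#'
#' `effect_additive(gamma)` adds `gamma` to every treated subject's
#' continuous outcome; `effect_multiplicative(multiplier)` multiplies every
#' treated subject's observed time — event or censoring time alike — by the
#' positive `multiplier` (the survival effect size / AFT time ratio).
#'
#' @param gamma Additive effect on the outcome scale.
#' @param multiplier Positive time ratio.
#' @return An `effect_spec` object.
#' @export
effect_additive <- function(gamma) {
  stopifnot(is.finite(gamma))
  structure(list(type = "additive", value = gamma), class = "effect_spec")
}

#' @rdname effect_additive
#' @export
effect_multiplicative <- function(multiplier) {
  if (!is.finite(multiplier) || multiplier <= 0)
    stop("'multiplier' must be positive", call. = FALSE)
  structure(list(type = "multiplicative", value = multiplier),
            class = "effect_spec")
}

#' Resample one plasmode trial from a split cohort
#'
#' Draws a simulated two-arm trial of total size `n` (exactly `n/2` per
#' arm): the control arm samples `(x, outcome)` pairs with replacement from
#' the control source and keeps the outcomes untouched (`a = 0`); the
#' treated arm samples from the treated source (`a = 1`) and receives the
#' injected artificial effect — `gamma` added to continuous outcomes, or
#' all observed times (event and censoring) multiplied by the time ratio.
#' For survival cohorts an optional administrative horizon then truncates
#' every time at `admin_censor_time` months with the event marked
#' unobserved.
#'
#' @param split A [split_cohort()] result.
#' @param n Even total trial size.
#' @param effect An [effect_additive()] (continuous cohorts) or
#'   [effect_multiplicative()] (survival cohorts).
#' @param admin_censor_time Optional end-of-study horizon in months;
#'   survival cohorts only.
#' @param seed Optional integer seed (same subject-major stream contract as
#'   the synthetic generators).
#' @return A [continuous_trial()] or [survival_trial()].
#' @export
resample_trial <- function(split, n, effect, admin_censor_time = NULL,
                           seed = NULL) {
  stopifnot(inherits(split, "plasmode_split"), inherits(effect, "effect_spec"))
  if (n %% 2 != 0 || n < 4)
    stop("'n' must be an even total of at least 4 (n/2 subjects per arm)",
         call. = FALSE)
  type <- outcome_type(split$source_control)
  if (type == "continuous" && effect$type != "additive")
    stop("continuous cohorts take an additive effect (see effect_additive())",
         call. = FALSE)
  if (type == "survival" && effect$type != "multiplicative")
    stop("survival cohorts take a multiplicative time effect (see ",
         "effect_multiplicative())", call. = FALSE)
  if (!is.null(admin_censor_time)) {
    if (type == "continuous")
      stop("'admin_censor_time' applies only to survival cohorts", call. = FALSE)
    stopifnot(admin_censor_time > 0)
  }
  m <- n / 2
  z <- subject_stream(m, 2L, seed)    # one control and one treated draw per pair
  u_ctrl <- stats::pnorm(z[1L, ])
  u_trt <- stats::pnorm(z[2L, ])
  idx_c <- pmin(nrow(split$source_control),
                floor(u_ctrl * nrow(split$source_control)) + 1L)
  idx_t <- pmin(nrow(split$source_treated),
                floor(u_trt * nrow(split$source_treated)) + 1L)
  ctrl <- split$source_control[idx_c, , drop = FALSE]
  trt <- split$source_treated[idx_t, , drop = FALSE]
  a <- rep(c(0, 1), each = m)
  x <- c(ctrl$x, trt$x)
  if (type == "continuous") {
    continuous_trial(y = c(ctrl$y, trt$y + effect$value), x = x, a = a)
  } else {
    time <- c(ctrl$time, trt$time * effect$value)
    event <- c(ctrl$event, trt$event)
    if (!is.null(admin_censor_time)) {
      # a subject reaching the horizon exactly is recorded as censored
      over <- time >= admin_censor_time
      event[over] <- 0
      time[over] <- admin_censor_time
    }
    survival_trial(time = time, event = event, x = x, a = a)
  }
}
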