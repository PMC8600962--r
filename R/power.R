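#' Describe one Monte-Carlo simulation setting
#'
#' Couples a [trial generator][trial_generators] with the analysis to run on
#' each simulated trial and the global testing conventions (two-sided
#' alpha = 0.05, 1000 repetitions by default).
#'
#' @param generator A `trial_generator`.
#' @param analysis `"adjusted"` (include the baseline score) or
#'   `"unadjusted"`.
#' @param dist AFT error law for survival analyses, `"loglogistic"`
#'   (default) or `"weibull"`; ignored for continuous outcomes.
#' @param alpha Two-sided significance level, in (0, 1).
#' @param n_reps Monte-Carlo repetitions (at least 100).
#' @param effect_convention How [effect_to_gamma()] maps a continuous
#'   effect size to the model-scale \eqn{\gamma}: `"sd"` (default;
#'   effect size times the outcome SD, i.e. a standardized effect) or
#'   `"gamma"` (the effect size *is* \eqn{\gamma}). Ignored for survival
#'   outcomes, whose effect size is always the raw time ratio.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(generator, analysis = c("adjusted", "unadjusted"),
                            dist = c("loglogistic", "weibull"), alpha = 0.05,
                            n_reps = 1000,
                            effect_convention = c("sd", "gamma")) {
  stopifnot(inherits(generator, "trial_generator"))
  analysis <- match.arg(analysis)
  dist <- match.arg(dist)
  effect_convention <- match.arg(effect_convention)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (n_reps < 100) stop("'n_reps' must be at least 100", call. = FALSE)
  structure(list(generator = generator, analysis = analysis, dist = dist,
                 alpha = alpha, n_reps = as.integer(n_reps),
                 effect_convention = effect_convention),
            class = "simulation_spec")
}

#' Convert an effect size to the model scale
#'
#' Continuous outcomes: under the `"sd"` convention the effect size is a
#' standardized effect and \eqn{\gamma = \mathrm{ES} \times \mathrm{SD}(Y)},
#' with SD(Y) the closed-form marginal SD of the synthetic process or the
#' empirical SD of the full plasmode cohort (computed before splitting).
#' Under the `"gamma"` convention the effect size is already \eqn{\gamma}.
#' Survival outcomes: the effect size is the multiplicative time ratio and
#' passes through unchanged (its AFT-coefficient counterpart is its log);
#' it must be positive.
#'
#' @param effect_size Effect size on the reporting scale.
#' @param generator A `trial_generator` (carries the outcome SD).
#' @param convention `"sd"` or `"gamma"`; continuous outcomes only.
#' @return The model-scale effect handed to the generator.
#' @export
effect_to_gamma <- function(effect_size, generator,
                            convention = c("sd", "gamma")) {
  stopifnot(inherits(generator, "trial_generator"))
  convention <- match.arg(convention)
  if (generator$type == "survival") {
    if (!is.finite(effect_size) || effect_size <= 0)
      stop("a survival effect size is a time ratio and must be positive",
           call. = FALSE)
    return(effect_size)
  }
  if (convention == "sd") effect_size * generator$outcome_sd else effect_size
}

# deterministic per-repetition seed stream: shared across n and across the
# adjusted/unadjusted analyses whenever the experiment seed matches (common
# random numbers)
rep_seed_stream <- function(seed, n_reps) {
  set.seed(seed)
  sample.int(2147483646L, n_reps)
}

analyze_trial <- function(trial, analysis, dist) {
  adjusted <- analysis == "adjusted"
  if (inherits(trial, "continuous_trial")) {
    fit_linear(trial, adjusted = adjusted)
  } else {
    fit_aft(trial, adjusted = adjusted, dist = dist)
  }
}

#' Monte-Carlo power (or type-I error) at one trial size
#'
#' Runs `n_reps` generate-fit-test cycles with a deterministic per-rep seed
#' stream and reports the fraction of converged fits whose two-sided Wald
#' p-value falls below `alpha`. With a null effect (0 for continuous, 1 for
#' survival) the estimate is the empirical type-I error. Non-converged fits
#' are excluded from the denominator and counted; a degenerate adjusted fit
#' (zero score variance in a bootstrap draw) falls back to the unadjusted
#' model and is counted in `n_fallback`.
#'
#' @param spec A [simulation_spec()].
#' @param n Total trial size.
#' @param effect_size Effect size on the reporting scale (see
#'   [effect_to_gamma()]).
#' @param seed Integer experiment seed; identical seeds give bit-identical
#'   results and common random numbers across analyses and trial sizes.
#' @return An object of class `power_estimate`: list with `n`,
#'   `effect_size`, `power`, `mc_se` (binomial SE), `n_reps_used`,
#'   `n_reps`, `n_fallback`, `alpha`, `analysis`, `nonconvergence_high`.
#' @export
estimate_power <- function(spec, n, effect_size, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  eff <- effect_to_gamma(effect_size, spec$generator, spec$effect_convention)
  seeds <- rep_seed_stream(seed, spec$n_reps)
  rejected <- 0L
  used <- 0L
  fallback <- 0L
  for (r in seq_len(spec$n_reps)) {
    trial <- spec$generator$generate(n, eff, seeds[r])
    fit <- tryCatch(
      analyze_trial(trial, spec$analysis, spec$dist),
      error = function(e) {
        if (spec$analysis == "adjusted" &&
            grepl("singular|zero-variance", conditionMessage(e))) {
          fallback <<- fallback + 1L
          tryCatch(analyze_trial(trial, "unadjusted", spec$dist),
                   error = function(e2) NULL)
        } else NULL
      })
    if (is.null(fit) || !isTRUE(fit$converged)) next
    used <- used + 1L
    if (fit$p_value < spec$alpha) rejected <- rejected + 1L
  }
  power <- if (used > 0) rejected / used else NA_real_
  high <- used < 0.95 * spec$n_reps
  if (high)
    warning(sprintf("more than 5%% of fits failed to converge at n = %d (%d of %d used)",
                    n, used, spec$n_reps), call. = FALSE)
  structure(list(n = as.integer(n), effect_size = effect_size, power = power,
                 mc_se = if (used > 0) sqrt(power * (1 - power) / used) else NA_real_,
                 n_reps_used = used, n_reps = spec$n_reps,
                 n_fallback = fallback, alpha = spec$alpha,
                 analysis = spec$analysis,
                 nonconvergence_high = high),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> n = %d, effect = %g, %s analysis\n",
              x$n, x$effect_size, x$analysis))
  cat(sprintf("  power = %.3f (MC se %.3f), %d/%d converged reps\n",
              x$power, x$mc_se, x$n_reps_used, x$n_reps))
  invisible(x)
}

even_floor <- function(n) 2L * (as.integer(n) %/% 2L)

#' Smallest trial size reaching a target power
#'
#' Ascending coarse scan over `seq(n_start, n_stop, n_step)` stopping at the
#' first size whose Monte-Carlo power estimate reaches `target_power`,
#' followed by bisection between the bracketing grid points down to
#' `resolution` (kept even: arms of `n/2`). The per-rep seed stream is
#' reused at every size (common random numbers), so the power trace is far
#' smoother than independent estimates would be and its first crossing is a
#' stable minimum-n estimate. `smooth = "isotonic"` optionally replaces the
#' scanned trace by its isotonic regression before the crossing is located,
#' guarding against noise-induced early crossings.
#'
#' @param spec A [simulation_spec()].
#' @param effect_size Effect size on the reporting scale.
#' @param target_power Target power, default 0.80.
#' @param n_start,n_stop,n_step Even scan grid of total trial sizes.
#' @param resolution Final even step of the bisection refinement (default 2,
#'   the finest possible with equal arms).
#' @param smooth `"none"` (first crossing of the raw trace) or
#'   `"isotonic"`.
#' @param seed Integer experiment seed.
#' @return An object of class `min_n_result`: list with `effect_size`,
#'   `min_n` (`NA` when the target is not reached within the grid),
#'   `reached`, `target_power`, `analysis` and the evaluated `trace`
#'   (data.frame of n, power, mc_se, n_reps_used).
#' @export
find_min_n <- function(spec, effect_size, target_power = 0.8,
                       n_start = 20, n_stop = 1000, n_step = 10,
                       resolution = 2, smooth = c("none", "isotonic"),
                       seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  smooth <- match.arg(smooth)
  if (target_power <= 0 || target_power >= 1)
    stop("'target_power' must lie in (0, 1)", call. = FALSE)
  if (n_step %% 2 != 0 || n_step <= 0)
    stop("'n_step' must be a positive even number (arms of n/2)", call. = FALSE)
  if (n_start %% 2 != 0 || n_stop < n_start)
    stop("'n_start' must be even and 'n_stop' must not precede it", call. = FALSE)
  resolution <- max(2L, even_floor(resolution))

  grid <- seq(n_start, n_stop, by = n_step)
  evals <- list()
  eval_at <- function(n) {
    key <- as.character(n)
    if (is.null(evals[[key]]))
      evals[[key]] <<- estimate_power(spec, n, effect_size, seed = seed)
    evals[[key]]
  }

  hit <- NA_integer_
  scanned <- integer(0)
  for (n in grid) {
    est <- eval_at(n)
    scanned <- c(scanned, n)
    pw <- est$power
    if (smooth == "isotonic" && length(scanned) > 1) {
      iso <- stats::isoreg(scanned,
                           vapply(scanned, function(m) eval_at(m)$power, 0))
      pw <- iso$yf[length(scanned)]
    }
    if (!is.na(pw) && pw >= target_power) { hit <- n; break }
  }

  if (is.na(hit)) {
    min_n <- NA_integer_
    reached <- FALSE
  } else if (hit == grid[1]) {
    min_n <- as.integer(hit)
    reached <- TRUE
  } else {
    lo <- hit - n_step       # power below target here (or unscanned edge)
    hi <- hit
    while (hi - lo > resolution) {
      mid <- even_floor((lo + hi) / 2)
      if (mid <= lo || mid >= hi) break
      if (eval_at(mid)$power >= target_power) hi <- mid else lo <- mid
    }
    min_n <- as.integer(hi)
    reached <- TRUE
  }

  ns <- sort(as.integer(names(evals)))
  trace <- data.frame(
    n = ns,
    power = vapply(as.character(ns), function(k) evals[[k]]$power, 0),
    mc_se = vapply(as.character(ns), function(k) evals[[k]]$mc_se, 0),
    n_reps_used = vapply(as.character(ns), function(k) evals[[k]]$n_reps_used, 0L),
    row.names = NULL)
  structure(list(effect_size = effect_size, min_n = min_n, reached = reached,
                 target_power = target_power, analysis = spec$analysis,
                 trace = trace),
            class = "min_n_result")
}

#' @export
print.min_n_result <- function(x, ...) {
  cat(sprintf("<min_n_result> effect = %g, %s analysis, target power %.0f%%\n",
              x$effect_size, x$analysis, 100 * x$target_power))
  if (x$reached) {
    cat(sprintf("  minimum total sample size: %d\n", x$min_n))
  } else {
    cat("  target power not reached within the searched grid\n")
  }
  cat(sprintf("  (%d sizes evaluated)\n", nrow(x$trace)))
  invisible(x)
}

#' Minimum-sample-size curve over a grid of effect sizes
#'
#' For every effect size, runs the minimum-n search for both the
#' score-adjusted and the unadjusted analysis under common random numbers
#' (same experiment seed), yielding the sample-size-versus-effect-size
#' curve. A target not reached within the grid propagates as `NA`.
#'
#' @param generator A `trial_generator`.
#' @param effect_grid Non-empty vector of effect sizes.
#' @param target_power Target power, default 0.80.
#' @inheritParams find_min_n
#' @inheritParams simulation_spec
#' @return A `data.frame` of class `sample_size_curve` with columns
#'   `effect_size`, `min_n_adjusted`, `min_n_unadjusted`; search traces are
#'   attached as attribute `"traces"`.
#' @export
run_curve <- function(generator, effect_grid, target_power = 0.8,
                      n_start = 20, n_stop = 1000, n_step = 10,
                      resolution = 2, n_reps = 1000, alpha = 0.05,
                      dist = c("loglogistic", "weibull"),
                      effect_convention = c("sd", "gamma"),
                      smooth = c("none", "isotonic"), seed = 1L) {
  stopifnot(inherits(generator, "trial_generator"))
  if (length(effect_grid) < 1) stop("'effect_grid' must be non-empty", call. = FALSE)
  dist <- match.arg(dist)
  effect_convention <- match.arg(effect_convention)
  smooth <- match.arg(smooth)
  traces <- list()
  rows <- lapply(effect_grid, function(es) {
    res <- lapply(c("adjusted", "unadjusted"), function(an) {
      sp <- simulation_spec(generator, analysis = an, dist = dist,
                            alpha = alpha, n_reps = n_reps,
                            effect_convention = effect_convention)
      find_min_n(sp, es, target_power = target_power, n_start = n_start,
                 n_stop = n_stop, n_step = n_step, resolution = resolution,
                 smooth = smooth, seed = seed)
    })
    names(res) <- c("adjusted", "unadjusted")
    traces[[as.character(es)]] <<- res
    data.frame(effect_size = es,
               min_n_adjusted = res$adjusted$min_n,
               min_n_unadjusted = res$unadjusted$min_n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sample_size_curve", "data.frame")
  attr(out, "target_power") <- target_power
  attr(out, "traces") <- traces
  out
}

#' @export
print.sample_size_curve <- function(x, ...) {
  cat(sprintf("<sample_size_curve> target power %.0f%%\n",
              100 * attr(x, "target_power")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Tidy long form of a sample-size curve
#'
#' @param curve A [run_curve()] result.
#' @return A data.frame with columns `effect_size`, `analysis`,
#'   `target_power`, `min_n` (one row per effect size and analysis).
#' @export
tidy_curve <- function(curve) {
  stopifnot(inherits(curve, "sample_size_curve"))
  tp <- attr(curve, "target_power")
  data.frame(
    effect_size = rep(curve$effect_size, 2L),
    analysis = rep(c("adjusted", "unadjusted"), each = nrow(curve)),
    target_power = tp,
    min_n = c(curve$min_n_adjusted, curve$min_n_unadjusted))
}
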