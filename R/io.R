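#' Read an observational cohort from CSV
#'
#' Accepts exactly the two cohort schemas: `subject_id,x,y` (continuous
#' outcome) or `subject_id,x,time,event` (survival outcome, times in
#' months, event in 0/1). Validation is strict — unknown columns, missing
#' cells, non-positive times or out-of-range event codes raise descriptive
#' errors naming the offending rows; missingness is rejected, not imputed.
#'
#' @param path Path to a CSV file.
#' @return A [cohort()].
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cont_schema <- c("subject_id", "x", "y")
  surv_schema <- c("subject_id", "x", "time", "event")
  nm <- names(df)
  if (identical(nm, cont_schema)) {
    type <- "continuous"
  } else if (identical(nm, surv_schema)) {
    type <- "survival"
  } else {
    stop("unrecognized cohort schema: columns are [", paste(nm, collapse = ", "),
         "], expected [", paste(cont_schema, collapse = ", "), "] or [",
         paste(surv_schema, collapse = ", "), "]", call. = FALSE)
  }
  bad_rows <- function(flag) paste(which(flag), collapse = ", ")
  na_any <- !stats::complete.cases(df)
  if (any(na_any))
    stop("missing values in row(s) ", bad_rows(na_any), call. = FALSE)
  if (type == "survival") {
    if (any(df$time <= 0))
      stop("non-positive survival time in row(s) ", bad_rows(df$time <= 0),
           call. = FALSE)
    if (!all(df$event %in% c(0, 1)))
      stop("event indicator outside {0, 1} in row(s) ",
           bad_rows(!(df$event %in% c(0, 1))), call. = FALSE)
    cohort(x = df$x, time = df$time, event = df$event,
           subject_id = df$subject_id)
  } else {
    cohort(x = df$x, y = df$y, subject_id = df$subject_id)
  }
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]; the written file round-trips exactly.
#'
#' @param cohort A [cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Assemble and validate an experiment configuration
#'
#' One validated bundle of everything a sample-size experiment needs; it is
#' serialized alongside the results so every output directory can be
#' regenerated exactly. Modes: `synthetic-continuous`, `synthetic-survival`
#' (parameters via `dgp`), `plasmode-continuous`, `plasmode-survival`
#' (cohort via `cohort_path`).
#'
#' @param mode One of the four modes above.
#' @param effect_grid Effect sizes to scan.
#' @param n_start,n_stop,n_step Even total-size search grid.
#' @param n_reps Monte-Carlo repetitions per size.
#' @param alpha Two-sided significance level.
#' @param target_power Target power for the minimum-n search.
#' @param seed Experiment seed.
#' @param dist AFT error law for survival analyses.
#' @param effect_convention `"sd"` or `"gamma"` (continuous only; see
#'   [effect_to_gamma()]).
#' @param dgp A [continuous_dgp()] / [survival_dgp()], or `NULL` for
#'   defaults (synthetic modes).
#' @param cohort_path CSV path (plasmode modes).
#' @param admin_censor_time Optional horizon in months (plasmode survival
#'   only).
#' @param split_seed Seed of the fixed plasmode split; defaults to `seed`.
#' @param out_dir Output directory for [run_experiment()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic-continuous", "synthetic-survival",
                                "plasmode-continuous", "plasmode-survival"),
                       effect_grid, n_start = 20, n_stop = 1000, n_step = 10,
                       n_reps = 1000, alpha = 0.05, target_power = 0.8,
                       seed = 1L, dist = c("loglogistic", "weibull"),
                       effect_convention = c("sd", "gamma"), dgp = NULL,
                       cohort_path = NULL, admin_censor_time = NULL,
                       split_seed = NULL, out_dir = "progpower-results") {
  mode <- match.arg(mode)
  dist <- match.arg(dist)
  effect_convention <- match.arg(effect_convention)
  if (length(effect_grid) < 1 || anyNA(effect_grid))
    stop("'effect_grid' must be a non-empty numeric vector", call. = FALSE)
  plasmode <- startsWith(mode, "plasmode")
  continuous <- endsWith(mode, "continuous")
  if (plasmode && is.null(cohort_path))
    stop("plasmode modes require 'cohort_path'", call. = FALSE)
  if (!plasmode && !is.null(cohort_path))
    stop("'cohort_path' is only meaningful for plasmode modes", call. = FALSE)
  if (continuous && !is.null(admin_censor_time))
    stop("'admin_censor_time' applies only to survival cohorts", call. = FALSE)
  if (continuous && any(effect_grid < 0))
    stop("continuous effect sizes must be non-negative", call. = FALSE)
  if (!continuous && any(effect_grid <= 0))
    stop("survival effect sizes are time ratios and must be positive",
         call. = FALSE)
  if (!is.null(dgp)) {
    want <- if (continuous) "continuous_dgp" else "survival_dgp"
    if (!inherits(dgp, want))
      stop("'dgp' must be a ", want, " for mode ", mode, call. = FALSE)
    if (plasmode) stop("'dgp' is only meaningful for synthetic modes", call. = FALSE)
  }
  structure(list(mode = mode, effect_grid = as.numeric(effect_grid),
                 n_start = n_start, n_stop = n_stop, n_step = n_step,
                 n_reps = n_reps, alpha = alpha, target_power = target_power,
                 seed = as.integer(seed), dist = dist,
                 effect_convention = effect_convention, dgp = dgp,
                 cohort_path = cohort_path,
                 admin_censor_time = admin_censor_time,
                 split_seed = if (is.null(split_seed)) as.integer(seed)
                              else as.integer(split_seed),
                 out_dir = out_dir),
            class = "run_config")
}

config_generator <- function(config) {
  switch(config$mode,
    "synthetic-continuous" = synthetic_continuous_generator(
      if (is.null(config$dgp)) continuous_dgp() else config$dgp),
    "synthetic-survival" = synthetic_survival_generator(
      if (is.null(config$dgp)) survival_dgp() else config$dgp),
    {
      ch <- read_cohort_csv(config$cohort_path)
      want <- if (config$mode == "plasmode-continuous") "continuous" else "survival"
      if (outcome_type(ch) != want)
        stop("cohort at ", config$cohort_path, " has a ", outcome_type(ch),
             " outcome but mode is ", config$mode, call. = FALSE)
      plasmode_generator(ch, split_seed = config$split_seed,
                         admin_censor_time = config$admin_censor_time)
    })
}

serializable_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$dgp)) out$dgp <- unclass(out$dgp)
  out[!vapply(out, is.null, TRUE)]
}

#' Run a full sample-size experiment and write its artifacts
#'
#' Builds the generator from the configuration, runs [run_curve()] over the
#' effect grid, and writes to `config$out_dir`: `curve.csv` (tidy rows
#' `effect_size,analysis,target_power,min_n`), `traces.csv` (every
#' evaluated (n, power) pair of every search), `config.yaml` (the resolved
#' configuration) and `run.log` (seed, package version, timing). Identical
#' configurations and seeds produce identical `curve.csv`, `traces.csv`
#' and `config.yaml`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages?
#' @return The [run_curve()] result, invisibly.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  gen <- config_generator(config)
  curve <- run_curve(gen, config$effect_grid,
                     target_power = config$target_power,
                     n_start = config$n_start, n_stop = config$n_stop,
                     n_step = config$n_step, n_reps = config$n_reps,
                     alpha = config$alpha, dist = config$dist,
                     effect_convention = config$effect_convention,
                     seed = config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tidy_curve(curve),
                   file.path(config$out_dir, "curve.csv"), row.names = FALSE)
  traces <- attr(curve, "traces")
  trace_rows <- do.call(rbind, lapply(names(traces), function(es) {
    do.call(rbind, lapply(c("adjusted", "unadjusted"), function(an) {
      tr <- traces[[es]][[an]]$trace
      if (nrow(tr) == 0) return(NULL)
      cbind(effect_size = as.numeric(es), analysis = an, tr)
    }))
  }))
  utils::write.csv(trace_rows, file.path(config$out_dir, "traces.csv"),
                   row.names = FALSE)
  yaml::write_yaml(serializable_config(config),
                   file.path(config$out_dir, "config.yaml"))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  writeLines(c(
    sprintf("progpower %s", as.character(utils::packageVersion("progpower"))),
    sprintf("mode: %s", config$mode),
    sprintf("seed: %d", config$seed),
    sprintf("elapsed_sec: %.1f", elapsed)
  ), file.path(config$out_dir, "run.log"))
  if (!quiet)
    message(sprintf("experiment '%s' finished in %.1fs -> %s",
                    config$mode, elapsed, config$out_dir))
  invisible(curve)
}
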