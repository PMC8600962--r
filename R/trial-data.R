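#' Construct a two-arm trial with a continuous outcome
#'
#' A `continuous_trial` holds per-subject data for one (real or simulated)
#' randomized trial analysed on the outcome scale: the outcome `y` (for
#' example 2-year cognitive change), an optional baseline prognostic score
#' `x`, and the arm indicator `a` (0 = control, 1 = treated).
#'
#' @param y Numeric outcome, one value per subject.
#' @param x Numeric baseline prognostic score per subject, or `NULL` if the
#'   trial carries no score (only unadjusted analyses are then possible).
#' @param a Integer/numeric arm indicator per subject, coded 0/1.
#'
#' @return An object of class `continuous_trial`: a list with elements
#'   `y`, `x`, `a` and `n`.
#' @examples
#' tr <- continuous_trial(y = c(1, 3, 2, 4), x = NULL, a = c(0, 0, 1, 1))
#' fit_linear(tr, adjusted = FALSE)
#' @export
continuous_trial <- function(y, x = NULL, a) {
  y <- as.numeric(y)
  a <- as.numeric(a)
  n <- length(y)
  if (n < 4L) stop("a trial needs at least 4 subjects", call. = FALSE)
  if (length(a) != n) stop("'y' and 'a' must have equal length", call. = FALSE)
  if (!is.null(x)) {
    x <- as.numeric(x)
    if (length(x) != n) stop("'x' must match 'y' in length", call. = FALSE)
    if (anyNA(x) || any(!is.finite(x))) stop("'x' contains missing or non-finite values", call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) stop("'y' contains missing or non-finite values", call. = FALSE)
  check_arm(a)
  structure(list(y = y, x = x, a = a, n = n), class = "continuous_trial")
}

#' Construct a two-arm trial with a right-censored survival outcome
#'
#' A `survival_trial` holds per-subject follow-up data: the observed time
#' (months), the event indicator (1 = event observed, 0 = right-censored),
#' an optional baseline prognostic score `x`, and the arm indicator `a`.
#'
#' @param time Positive follow-up time per subject, in months.
#' @param event Event indicator per subject, 0/1; at least one event overall.
#' @param x Numeric baseline prognostic score per subject, or `NULL`.
#' @param a Arm indicator per subject, coded 0/1; both arms represented.
#'
#' @return An object of class `survival_trial`: a list with elements
#'   `time`, `event`, `x`, `a` and `n`.
#' @export
survival_trial <- function(time, event, x = NULL, a) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  a <- as.numeric(a)
  n <- length(time)
  if (n < 4L) stop("a trial needs at least 4 subjects", call. = FALSE)
  if (length(event) != n || length(a) != n)
    stop("'time', 'event' and 'a' must have equal length", call. = FALSE)
  if (!is.null(x)) {
    x <- as.numeric(x)
    if (length(x) != n) stop("'x' must match 'time' in length", call. = FALSE)
    if (anyNA(x) || any(!is.finite(x))) stop("'x' contains missing or non-finite values", call. = FALSE)
  }
  if (anyNA(time) || any(!is.finite(time)) || any(time <= 0))
    stop("'time' must be strictly positive and finite", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("'event' must contain only 0/1", call. = FALSE)
  if (sum(event) < 1) stop("all subjects are censored: at least one event is required", call. = FALSE)
  check_arm(a)
  structure(list(time = time, event = event, x = x, a = a, n = n),
            class = "survival_trial")
}

check_arm <- function(a) {
  if (!all(a %in% c(0, 1))) stop("'a' must contain only 0/1", call. = FALSE)
  if (sum(a == 0) < 1 || sum(a == 1) < 1)
    stop("both arms must contain at least one subject", call. = FALSE)
  invisible(TRUE)
}

#' Construct an observational cohort
#'
#' A cohort is the source material for plasmode simulation: one row per
#' subject, with a baseline prognostic score and either a continuous outcome
#' (`y`) or a right-censored survival outcome (`time`, `event`). Missing
#' values are rejected outright.
#'
#' @param x Numeric prognostic score per subject.
#' @param y Continuous outcome (give exactly one of `y` or `time`+`event`).
#' @param time,event Survival outcome: positive times (months) and 0/1
#'   event indicators.
#' @param subject_id Optional identifiers; defaults to `1:n`.
#'
#' @return A `data.frame` of class `cohort` with attribute `outcome_type`
#'   (`"continuous"` or `"survival"`).
#' @seealso [gen_synthetic_cohort()], [read_cohort_csv()], [split_cohort()]
#' @export
cohort <- function(x, y = NULL, time = NULL, event = NULL, subject_id = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(subject_id)) subject_id <- seq_len(n)
  if (length(subject_id) != n) stop("'subject_id' must match 'x' in length", call. = FALSE)
  if (anyDuplicated(subject_id)) stop("'subject_id' must be unique", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("'x' contains missing or non-finite values", call. = FALSE)
  continuous <- !is.null(y)
  if (continuous && (!is.null(time) || !is.null(event)))
    stop("give either 'y' or ('time', 'event'), not both", call. = FALSE)
  if (continuous) {
    y <- as.numeric(y)
    if (length(y) != n) stop("'y' must match 'x' in length", call. = FALSE)
    if (anyNA(y) || any(!is.finite(y))) stop("'y' contains missing or non-finite values", call. = FALSE)
    out <- data.frame(subject_id = subject_id, x = x, y = y)
    type <- "continuous"
  } else {
    if (is.null(time) || is.null(event))
      stop("a survival cohort needs both 'time' and 'event'", call. = FALSE)
    time <- as.numeric(time); event <- as.numeric(event)
    if (length(time) != n || length(event) != n)
      stop("'time' and 'event' must match 'x' in length", call. = FALSE)
    if (anyNA(time) || any(!is.finite(time)) || any(time <= 0))
      stop("'time' must be strictly positive and finite", call. = FALSE)
    if (!all(event %in% c(0, 1))) stop("'event' must contain only 0/1", call. = FALSE)
    out <- data.frame(subject_id = subject_id, x = x, time = time, event = event)
    type <- "survival"
  }
  structure(out, class = c("cohort", "data.frame"), outcome_type = type)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %s outcome\n", nrow(x), outcome_type(x)))
  if (outcome_type(x) == "survival")
    cat(sprintf("  events: %d (%.0f%% censored)\n", sum(x$event),
                100 * mean(x$event == 0)))
  NextMethod()
}

#' Outcome type of a cohort
#' @param x A [cohort()].
#' @return `"continuous"` or `"survival"`.
#' @export
outcome_type <- function(x) attr(x, "outcome_type")

# keep the cohort class and outcome_type attribute through row subsetting
#' @export
`[.cohort` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- c("cohort", "data.frame")
    attr(out, "outcome_type") <- attr(x, "outcome_type")
  }
  out
}
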