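# Daily pedometer QC: wear-time validity, truncation, and averaging over the
# longest run of consecutive valid days.

STEP_TRUNCATION_CAP <- 20000L

#' Wear-time validity of a single pedometer day
#'
#' A day is valid when the step count exceeds 100 (strictly) and the device
#' was worn for at least 8 hours.
#'
#' @param steps steps recorded that day (numeric vector, >= 0).
#' @param wear_hours hours the pedometer was worn (0-24), vectorized with
#'   `steps`.
#' @return Logical vector.
#' @examples
#' is_valid_day(100, 10)   # FALSE: need > 100 counts
#' is_valid_day(5000, 7.9) # FALSE: under 8 h wear
#' is_valid_day(101, 8)    # TRUE
#' @export
is_valid_day <- function(steps, wear_hours) {
  stopifnot(is.numeric(steps), is.numeric(wear_hours),
            length(steps) == length(wear_hours))
  if (any(steps < 0, na.rm = TRUE)) stopf("`steps` must be >= 0")
  if (any(wear_hours < 0 | wear_hours > 24, na.rm = TRUE)) {
    stopf("`wear_hours` must lie in [0, 24]")
  }
  !is.na(steps) & !is.na(wear_hours) & steps > 100 & wear_hours >= 8
}

#' Truncate implausibly high daily step counts
#'
#' Counts above 20,000 steps/day are set to 20,000 to avoid unrealistically
#' high values. Idempotent and monotone.
#'
#' @param steps numeric vector of daily step counts (>= 0).
#' @return Vector with values capped at 20,000.
#' @examples
#' truncate_steps(c(21500, 20000, 0))
#' @export
truncate_steps <- function(steps) {
  stopifnot(is.numeric(steps))
  if (any(steps < 0, na.rm = TRUE)) stopf("`steps` must be >= 0")
  pmin(steps, STEP_TRUNCATION_CAP)
}

#' Assemble a participant-wave step series
#'
#' @param dates calendar dates (`Date` or ISO-8601 strings), unique; at most 7
#'   per one-week measurement wave.
#' @param steps daily step counts.
#' @param wear_hours daily wear time in hours.
#' @param participant_id optional identifier carried through summaries.
#' @return A `step_series` tibble sorted by date with columns `date`, `steps`,
#'   `wear_hours` (plus `participant_id` attribute).
#' @export
step_series <- function(dates, steps, wear_hours, participant_id = NA_character_) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(steps), length(steps) == length(wear_hours))
  if (anyNA(dates)) stopf("`dates` contains unparseable values")
  if (anyDuplicated(dates)) stopf("`dates` must be unique within a wave")
  if (length(dates) > 7) stopf("a measurement wave holds at most 7 days")
  ord <- order(dates)
  out <- tibble::tibble(date = dates[ord], steps = as.numeric(steps)[ord],
                        wear_hours = as.numeric(wear_hours)[ord])
  attr(out, "participant_id") <- participant_id
  class(out) <- c("step_series", class(out))
  out
}

# maximal runs of consecutive calendar dates where `keep` is TRUE;
# returns list of index vectors, longest first (first on ties)
consecutive_runs <- function(dates, keep) {
  idx <- which(keep)
  if (length(idx) == 0) return(list())
  d <- as.integer(dates[idx])
  brk <- c(TRUE, diff(d) != 1L)
  grp <- cumsum(brk)
  runs <- split(idx, grp)
  runs[order(-lengths(runs), vapply(runs, min, 1L))]
}

#' Average daily steps over the longest valid run
#'
#' Locates the longest run of consecutive calendar days that are all valid
#' (see [is_valid_day()]). If the run spans at least 5 days - and, when
#' `require_weekend`, contains at least one Saturday or Sunday - the mean of
#' the truncated step counts over that run is returned; otherwise the series
#' is marked invalid with a reason code (`empty`, `too_few_consecutive`,
#' `no_weekend_day`).
#'
#' @param series a [step_series()].
#' @param require_weekend logical; demand >= 1 weekend day in the run
#'   (default `TRUE`, the wearing protocol).
#' @param min_days minimum run length (default 5 consecutive days).
#' @return List with `valid` (logical), `avg_steps` (steps/day or `NA`),
#'   `n_days`, and `reason` (`NA` when valid).
#' @examples
#' s <- step_series(as.Date("2024-03-04") + 0:6, rep(8000, 7), rep(12, 7))
#' average_daily_steps(s)$avg_steps
#' @export
average_daily_steps <- function(series, require_weekend = TRUE, min_days = 5L) {
  stopifnot(inherits(series, "step_series"))
  invalid <- function(reason) {
    list(valid = FALSE, avg_steps = NA_real_, n_days = 0L, reason = reason)
  }
  if (nrow(series) == 0) return(invalid("empty"))
  ok <- is_valid_day(series$steps, series$wear_hours)
  runs <- consecutive_runs(series$date, ok)
  if (length(runs) == 0 || length(runs[[1]]) < min_days) {
    return(invalid("too_few_consecutive"))
  }
  run <- runs[[1]]
  if (require_weekend) {
    wd <- format(series$date[run], "%u")  # 6 = Saturday, 7 = Sunday
    if (!any(wd %in% c("6", "7"))) {
      # fall back to the longest qualifying run containing a weekend day
      with_we <- Filter(function(r) {
        length(r) >= min_days &&
          any(format(series$date[r], "%u") %in% c("6", "7"))
      }, runs)
      if (length(with_we) == 0) return(invalid("no_weekend_day"))
      run <- with_we[[1]]
    }
  }
  list(valid = TRUE,
       avg_steps = mean(truncate_steps(series$steps[run])),
       n_days = length(run),
       reason = NA_character_)
}

#' Reconstruct wear hours from an activity log
#'
#' The pedometer does not record wear time; it is reconstructed as
#' `24 - sleep_hours - logged non-wear hours`, floored at 0. Non-walking
#' activities (kind other than `"nonwear"`) are kept as annotations and do
#' not affect wear time.
#'
#' @param series a [step_series()].
#' @param log data frame with columns `date`, `hours`, `kind`
#'   (`"nonwear"` or an activity label such as `"swimming"`).
#' @param sleep_hours assumed nightly sleep window (default 8 h).
#' @return The series with recomputed `wear_hours` and an `annotations`
#'   attribute holding the non-walking activity entries.
#' @examples
#' s <- step_series(as.Date("2024-03-04") + 0:6, rep(8000, 7), rep(16, 7))
#' log <- data.frame(date = as.Date("2024-03-05"), hours = 2, kind = "nonwear")
#' merge_activity_log(s, log)$wear_hours
#' @export
merge_activity_log <- function(series, log, sleep_hours = 8) {
  stopifnot(inherits(series, "step_series"))
  if (is.null(log) || nrow(log) == 0) return(series)
  stopifnot(all(c("date", "hours", "kind") %in% names(log)))
  log$date <- as.Date(log$date)
  outside <- !log$date %in% series$date
  if (any(outside)) {
    stopf("activity log dates outside the measurement window: %s",
          paste(format(log$date[outside]), collapse = ", "))
  }
  nonwear <- log[log$kind == "nonwear", , drop = FALSE]
  nw_by_day <- tapply(nonwear$hours, as.character(nonwear$date), sum)
  key <- as.character(series$date)
  nw <- ifelse(key %in% names(nw_by_day), nw_by_day[key], 0)
  series$wear_hours <- pmax(24 - sleep_hours - as.numeric(nw), 0)
  attr(series, "annotations") <- log[log$kind != "nonwear", , drop = FALSE]
  series
}

#' Per-participant pedometer QC summary for a step-log table
#'
#' Applies [average_daily_steps()] to every participant-wave group of a long
#' step log.
#'
#' @param steps_log data frame with columns `participant_id`, `wave`, `date`,
#'   `steps`, `wear_hours`.
#' @param require_weekend passed to [average_daily_steps()].
#' @return Tibble with one row per participant x wave: `avg_steps`,
#'   `n_valid_days`, `valid`, `reason`.
#' @export
summarize_step_log <- function(steps_log, require_weekend = TRUE) {
  needed <- c("participant_id", "wave", "date", "steps", "wear_hours")
  stopifnot(all(needed %in% names(steps_log)))
  groups <- split(steps_log, interaction(steps_log$participant_id,
                                         steps_log$wave, drop = TRUE))
  rows <- lapply(groups, function(g) {
    s <- step_series(g$date, g$steps, g$wear_hours, g$participant_id[1])
    res <- average_daily_steps(s, require_weekend = require_weekend)
    tibble::tibble(participant_id = g$participant_id[1], wave = g$wave[1],
                   avg_steps = res$avg_steps, n_valid_days = res$n_days,
                   valid = res$valid, reason = res$reason)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$participant_id, out$wave), ]
}
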