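# IPAQ short-form scoring: cleaning per the public IPAQ scoring protocol,
# conversion to minutes/day, totals, and the skewness-driven log transform.

IPAQ_DOMAINS <- c("walking", "moderate", "vigorous")

#' Construct an IPAQ short-form response
#'
#' @param days_walking,days_moderate,days_vigorous days/week (0-7) with at
#'   least 10 minutes of the activity.
#' @param min_walking,min_moderate,min_vigorous minutes/day on active days.
#' @param sitting_minutes minutes/day spent sitting.
#' @return Object of class `ipaq_response`.
#' @examples
#' ipaq_response(5, 42, 3, 30, 0, 0, 480)
#' @export
ipaq_response <- function(days_walking, min_walking,
                          days_moderate, min_moderate,
                          days_vigorous, min_vigorous,
                          sitting_minutes) {
  days <- c(walking = days_walking, moderate = days_moderate,
            vigorous = days_vigorous)
  mins <- c(walking = min_walking, moderate = min_moderate,
            vigorous = min_vigorous)
  if (any(days < 0 | days > 7)) stopf("days/week must lie in [0, 7]")
  if (any(mins < 0) || sitting_minutes < 0) stopf("minutes must be >= 0")
  structure(
    list(days = days, minutes = mins, sitting_minutes = sitting_minutes,
         excluded = FALSE, cleaned = FALSE),
    class = "ipaq_response"
  )
}

#' Clean an IPAQ response per the scoring protocol
#'
#' Applies the standard IPAQ data-processing rules: per-domain episodes under
#' 10 min/day are set to 0 (below the instrument's minimum bout), per-domain
#' minutes are truncated at 180 min/day (3 h), and respondents whose raw
#' walking + moderate + vigorous minutes exceed 960 min/day (16 h) are
#' flagged `excluded`. Exclusion is a flag, not an error, and is judged on
#' the raw minutes before truncation. Idempotent.
#'
#' @param response an [ipaq_response()].
#' @param min_bout minutes/day below which a domain is zeroed (default 10).
#' @param max_minutes per-domain truncation cap in minutes/day (default 180).
#' @param exclusion_total total raw minutes/day above which the respondent is
#'   flagged excluded (default 960).
#' @return The cleaned `ipaq_response` (fields `cleaned`, `excluded` set).
#' @examples
#' r <- clean_ipaq(ipaq_response(7, 8, 5, 240, 0, 0, 400))
#' r$minutes  # walking zeroed, moderate capped at 180
#' @export
clean_ipaq <- function(response, min_bout = 10, max_minutes = 180,
                       exclusion_total = 960) {
  stopifnot(inherits(response, "ipaq_response"))
  if (isTRUE(response$cleaned)) return(response)
  response$excluded <- sum(response$minutes) > exclusion_total
  m <- response$minutes
  m[m < min_bout] <- 0
  m <- pmin(m, max_minutes)
  response$minutes <- m
  response$cleaned <- TRUE
  response
}

#' Weekly frequency and duration to minutes/day
#'
#' @param days days/week the activity was performed (0-7).
#' @param minutes minutes/day on active days.
#' @return Average minutes/day over the whole week: `days * minutes / 7`.
#' @examples
#' minutes_per_day(5, 42)  # 30
#' @export
minutes_per_day <- function(days, minutes) {
  stopifnot(is.numeric(days), is.numeric(minutes))
  if (any(days < 0 | days > 7)) stopf("`days` must lie in [0, 7]")
  if (any(minutes < 0)) stopf("`minutes` must be >= 0")
  days * minutes / 7
}

#' Score an IPAQ response in minutes/day
#'
#' @param response an [ipaq_response()]; cleaned first if not already.
#' @return Named numeric vector: `walking`, `moderate`, `vigorous`,
#'   `total_pa`, `sitting` (all minutes/day), plus attribute `excluded`.
#' @export
score_ipaq <- function(response) {
  response <- clean_ipaq(response)
  per_domain <- minutes_per_day(response$days, response$minutes)
  out <- c(per_domain, total_pa = sum(per_domain),
           sitting = response$sitting_minutes)
  attr(out, "excluded") <- response$excluded
  out
}

#' Total physical activity in minutes/day
#'
#' Sum of walking, moderate and vigorous minutes/day after cleaning.
#'
#' @param response an [ipaq_response()].
#' @return Minutes/day.
#' @examples
#' total_pa(ipaq_response(7, 30, 7, 20, 7, 10, 400))  # 60
#' @export
total_pa <- function(response) {
  s <- score_ipaq(response)
  unname(s[["total_pa"]])
}

#' Log-transform a sample when a normality screen fails
#'
#' Physical-activity outcomes are typically positively skewed; following
#' common practice the sample is screened with a one-sample
#' Kolmogorov-Smirnov test against a normal with the sample's mean and SD,
#' and transformed to `log(x + 1)` when the screen rejects (p <= alpha). The
#' `+ 1` admits the zeros that are ubiquitous in self-reported activity. A
#' zero-variance sample cannot be screened and is returned untransformed.
#'
#' @param values numeric vector (minutes/day or steps/day), `n >= 8`.
#' @param alpha rejection level of the screen (default 0.05).
#' @return List with `values` (transformed or original), `decision`
#'   (`"transformed"`/`"untransformed"`), and `p_value` of the screen.
#' @examples
#' set.seed(1)
#' log_transform_if_skewed(rlnorm(200))$decision
#' @export
log_transform_if_skewed <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 8) stopf("need at least 8 non-missing values")
  s <- stats::sd(values)
  if (s == 0) {
    return(list(values = values, decision = "untransformed", p_value = NA_real_))
  }
  # exact = FALSE: daily-count data are tied; the asymptotic p is the screen
  p <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = s,
                   exact = FALSE)$p.value
  )
  if (p <= alpha) {
    if (any(values < -1)) stopf("log(x + 1) undefined for values < -1")
    list(values = log(values + 1), decision = "transformed", p_value = p)
  } else {
    list(values = values, decision = "untransformed", p_value = p)
  }
}

#' Score an IPAQ table
#'
#' @param ipaq_table data frame with columns `participant_id`, `wave`,
#'   `days_walk`, `min_walk`, `days_mod`, `min_mod`, `days_vig`, `min_vig`,
#'   `sit_min`.
#' @return Tibble with one row per input row: minutes/day per domain,
#'   `total_pa`, `sitting`, and the `excluded` flag.
#' @export
score_ipaq_table <- function(ipaq_table) {
  needed <- c("participant_id", "wave", "days_walk", "min_walk", "days_mod",
              "min_mod", "days_vig", "min_vig", "sit_min")
  stopifnot(all(needed %in% names(ipaq_table)))
  rows <- lapply(seq_len(nrow(ipaq_table)), function(i) {
    r <- ipaq_table[i, ]
    s <- score_ipaq(ipaq_response(r$days_walk, r$min_walk, r$days_mod,
                                  r$min_mod, r$days_vig, r$min_vig, r$sit_min))
    tibble::tibble(participant_id = r$participant_id, wave = r$wave,
                   walking = s[["walking"]], moderate = s[["moderate"]],
                   vigorous = s[["vigorous"]], total_pa = s[["total_pa"]],
                   sitting = s[["sitting"]], excluded = attr(s, "excluded"))
  })
  dplyr::bind_rows(rows)
}
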