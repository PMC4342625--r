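# Stage classification, step-goal scheduling and advice composition.
# The engine is deterministic: identical inputs yield byte-identical advice.

STEP_GOAL <- 10000L

#' Classify a participant's stage of change
#'
#' Standard transtheoretical staging against the 10,000 steps/day goal:
#' below-goal participants are staged on their intentions (no 6-month
#' intention -> precontemplation; 6-month but no 1-month intention ->
#' contemplation; 1-month intention -> preparation, the more proximal
#' intention dominating), at-goal participants on how long they have met the
#' goal (under 6 months or unknown -> action, 6 months or more ->
#' maintenance).
#'
#' @param response a [tailoring_response()].
#' @return A single stage label, see [stages_of_change()].
#' @examples
#' \dontrun{classify_stage(resp)}
#' @export
classify_stage <- function(response) {
  stopifnot(inherits(response, "tailoring_response"))
  steps <- response$avg_daily_steps
  if (steps >= STEP_GOAL) {
    months <- response$months_meeting_goal
    if (!is.null(months) && !is.na(months) && months >= 6) {
      return("maintenance")
    }
    return("action")
  }
  if (is.null(response$intent_1mo)) {
    stopf("cannot classify stage: `intent_1mo` missing for a below-goal participant")
  }
  if (response$intent_1mo == "yes") return("preparation")
  if (is.null(response$intent_6mo)) {
    stopf("cannot classify stage: `intent_6mo` missing for a below-goal participant")
  }
  if (response$intent_6mo == "yes") "contemplation" else "precontemplation"
}

#' Build a weekly step-goal schedule toward 10,000 steps/day
#'
#' Week `k`'s target is `baseline + k * increment`, capped at 10,000; the
#' schedule runs until the cap is reached. Participants already at or above
#' 10,000 steps/day get an empty schedule.
#'
#' @param baseline current average daily steps (>= 0).
#' @param increment weekly increase, 500 or 1000 steps (the participant's
#'   choice).
#' @return Object of class `step_schedule`: list with `baseline`, `increment`
#'   and integer vector `weekly_goals`.
#' @examples
#' generate_schedule(6700, 500)$weekly_goals
#' generate_schedule(10000, 1000)$weekly_goals  # empty: already at goal
#' @export
generate_schedule <- function(baseline, increment = 500) {
  assert_scalar_number(baseline, "baseline", min = 0)
  if (!increment %in% c(500, 1000)) {
    stopf("`increment` must be 500 or 1000 steps/week")
  }
  if (baseline >= STEP_GOAL) {
    goals <- integer(0)
  } else {
    n_weeks <- ceiling((STEP_GOAL - baseline) / increment)
    goals <- pmin(baseline + seq_len(n_weeks) * increment, STEP_GOAL)
    goals <- as.integer(goals)
  }
  structure(
    list(baseline = baseline, increment = increment, weekly_goals = goals),
    class = "step_schedule"
  )
}

#' @export
print.step_schedule <- function(x, ...) {
  cat("<step_schedule> baseline", x$baseline, "steps/day, +", x$increment,
      "steps/week\n")
  if (length(x$weekly_goals) == 0) {
    cat("  already at the 10,000 steps/day goal\n")
  } else {
    for (k in seq_along(x$weekly_goals)) {
      cat(sprintf("  week %d: %d steps/day\n", k, x$weekly_goals[k]))
    }
  }
  invisible(x)
}

#' Progress feedback between two advice requests
#'
#' Compares the step level at the previous request with the current one and
#' picks the improved / unchanged / declined message variant on the sign of
#' the difference. Deltas derived from fractional means are rounded half away
#' from zero.
#'
#' @param previous,current average daily steps at the two requests (>= 0).
#' @param bank a message bank, see [load_message_bank()].
#' @return List with `delta` (signed integer steps/day), `variant` and the
#'   rendered `text`.
#' @examples
#' progress_feedback(6697, 7753)$delta  # +1056
#' @export
progress_feedback <- function(previous, current, bank = load_message_bank()) {
  assert_scalar_number(previous, "previous", min = 0)
  assert_scalar_number(current, "current", min = 0)
  delta <- round_half_up(current - previous)
  variant <- if (delta > 0) "improved" else if (delta < 0) "declined" else "unchanged"
  id <- lookup_messages(bank, "progress", variant, stage = "*")
  text <- render_message(bank, id, list(
    previous = format(round_half_up(previous), big.mark = ","),
    current = format(round_half_up(current), big.mark = ","),
    delta = format(abs(delta), big.mark = ",")
  ))
  list(delta = delta, variant = variant, text = unname(text))
}

# Answer patterns per determinant; the keys the bank is indexed by.
determinant_patterns <- function(determinant, answers) {
  switch(determinant,
    intentions = {
      one <- answers$intent_1mo
      six <- answers$intent_6mo
      if (!is.null(one) && one == "yes") "plan_1mo"
      else if (!is.null(six) && six == "yes") "plan_6mo_only"
      else "no_plan"
    },
    attitudes = paste0(names(answers), ":", unname(answers)),
    self_efficacy = paste0(names(answers), ":", unname(answers)),
    social_support = c(
      paste0(names(answers$support), ":support:", unname(answers$support)),
      paste0(names(answers$active), ":active:", unname(answers$active))
    ),
    knowledge = {
      fam <- if (is.list(answers)) answers$pedometer_familiarity else answers
      if (identical(fam, "no")) "unfamiliar" else character(0)
    },
    benefits = as.character(answers),
    barriers = as.character(answers),
    stopf("unknown determinant `%s`", determinant)
  )
}

#' Select determinant-specific feedback messages
#'
#' Maps one determinant's answers to message identifiers in the bank. Barrier
#' selection returns exactly one message per chosen barrier; the pedometer
#' primer is returned iff the participant is unfamiliar with pedometers
#' (familiarity `"no"`), so `knowledge` with familiarity `"yes"` yields an
#' empty selection.
#'
#' @param determinant one of `intentions`, `attitudes`, `self_efficacy`,
#'   `social_support`, `knowledge`, `benefits`, `barriers`.
#' @param answers the determinant's answers: a named vector for item batteries
#'   (`attitudes`, `self_efficacy`), a list for `intentions`
#'   (`intent_6mo`/`intent_1mo`) and `social_support` (`support`/`active`), a
#'   single string for `knowledge` (familiarity) and `benefits`, a length-2
#'   vector for `barriers`.
#' @param stage the participant's stage of change (stage-specific message
#'   variants take precedence over wildcard ones).
#' @param bank a message bank, see [load_message_bank()].
#' @return Character vector of message identifiers (possibly empty only for
#'   `knowledge` with familiarity `"yes"`).
#' @examples
#' bank <- load_message_bank()
#' select_determinant_feedback("knowledge", "no", "preparation", bank)
#' @export
select_determinant_feedback <- function(determinant, answers, stage,
                                        bank = load_message_bank()) {
  check_level(stage, stages_of_change(), "stage")
  patterns <- determinant_patterns(determinant, answers)
  if (length(patterns) == 0) return(character(0))
  vapply(patterns, function(p) lookup_messages(bank, determinant, p, stage),
         character(1), USE.NAMES = FALSE)
}

DETERMINANT_ORDER <- c("intentions", "attitudes", "self_efficacy",
                       "social_support", "knowledge", "benefits", "barriers")

#' Compose the three-part computer-tailored step advice
#'
#' Assembles the full advice document: (1) a general introduction whose tone
#' follows the stage of change (impersonal for precontemplators, personal for
#' contemplators, directive for preparers, supportive for actors, a brief
#' congratulation for maintainers); (2) personalized feedback on the current
#' step count with a weekly schedule toward 10,000 steps/day; (3)
#' recommendations assembled from the determinant-matched messages. When a
#' previous step level is supplied, a progress note is added. Composition is
#' deterministic.
#'
#' @param response a [tailoring_response()].
#' @param bank a message bank, see [load_message_bank()].
#' @param increment weekly step increase preference (500 or 1000).
#' @return Object of class `advice_document` with elements `introduction`,
#'   `personal_feedback` (list of `text` and `schedule`), `recommendations`,
#'   `stage`, `progress_note` (or `NULL`) and `determinant_messages`.
#' @examples
#' \dontrun{doc <- compose_advice(resp); print(doc)}
#' @export
compose_advice <- function(response, bank = load_message_bank(),
                           increment = 500) {
  stopifnot(inherits(response, "tailoring_response"))
  stage <- classify_stage(response)
  steps_fmt <- format(round_half_up(response$avg_daily_steps), big.mark = ",")
  env <- list(steps = steps_fmt, goal = "10,000")

  intro_id <- lookup_messages(bank, "introduction", stage, "*")
  introduction <- unname(render_message(bank, intro_id, env))

  schedule <- generate_schedule(response$avg_daily_steps, increment)
  fb_pattern <- if (stage == "maintenance") "at_goal_maintenance"
                else if (stage == "action") "at_goal_action"
                else "below_goal"
  fb_id <- lookup_messages(bank, "feedback", fb_pattern, "*")
  fb_text <- unname(render_message(bank, fb_id, env))
  if (length(schedule$weekly_goals) > 0) {
    lines <- sprintf("Week %d: %s steps/day", seq_along(schedule$weekly_goals),
                     format(schedule$weekly_goals, big.mark = ",", trim = TRUE))
    fb_text <- paste(c(fb_text, lines), collapse = "\n")
  }

  answers <- list(
    intentions = list(intent_6mo = response$intent_6mo,
                      intent_1mo = response$intent_1mo),
    attitudes = response$attitudes,
    self_efficacy = response$self_efficacy,
    social_support = response$social_support,
    knowledge = response$pedometer_familiarity,
    benefits = response$benefit,
    barriers = response$barriers
  )
  determinant_messages <- lapply(DETERMINANT_ORDER, function(d) {
    select_determinant_feedback(d, answers[[d]], stage, bank)
  })
  names(determinant_messages) <- DETERMINANT_ORDER
  recommendations <- unname(unlist(lapply(determinant_messages, function(ids) {
    if (length(ids) == 0) character(0) else render_message(bank, ids, env)
  })))

  progress_note <- NULL
  if (!is.null(response$previous_avg_daily_steps)) {
    progress_note <- progress_feedback(response$previous_avg_daily_steps,
                                       response$avg_daily_steps, bank)$text
  }

  structure(
    list(
      introduction = introduction,
      personal_feedback = list(text = fb_text, schedule = schedule),
      recommendations = recommendations,
      stage = stage,
      progress_note = progress_note,
      determinant_messages = determinant_messages
    ),
    class = "advice_document"
  )
}

#' Render an advice document as Markdown
#'
#' @param doc an [compose_advice()] result.
#' @return A single Markdown string.
#' @export
advice_markdown <- function(doc) {
  stopifnot(inherits(doc, "advice_document"))
  parts <- c(
    "# Your personal step advice", "",
    "## Introduction", "", doc$introduction, "",
    "## Your steps", "", doc$personal_feedback$text, "",
    if (!is.null(doc$progress_note)) c(doc$progress_note, ""),
    "## Recommendations", "",
    paste0("- ", doc$recommendations)
  )
  paste(parts, collapse = "\n")
}

#' Render an advice document as minimal HTML
#'
#' @param doc an [compose_advice()] result.
#' @return A single HTML string.
#' @export
advice_html <- function(doc) {
  stopifnot(inherits(doc, "advice_document"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  p <- function(x) paste0("<p>", esc(x), "</p>")
  paste(c(
    "<html><body>", "<h1>Your personal step advice</h1>",
    "<h2>Introduction</h2>", p(doc$introduction),
    "<h2>Your steps</h2>",
    paste0("<p>", gsub("\n", "<br/>", esc(doc$personal_feedback$text)), "</p>"),
    if (!is.null(doc$progress_note)) p(doc$progress_note),
    "<h2>Recommendations</h2>", "<ul>",
    paste0("<li>", esc(doc$recommendations), "</li>"),
    "</ul>", "</body></html>"
  ), collapse = "\n")
}

#' @export
print.advice_document <- function(x, ...) {
  cat(advice_markdown(x), "\n")
  invisible(x)
}
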