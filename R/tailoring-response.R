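# Legal answer sets for the diagnostic questionnaire. The tailoring engine is
# a total function over these sets; the constructor rejects anything else.

#' Questionnaire answer sets
#'
#' The legal answers for every question of the psychosocial diagnostic
#' questionnaire that drives the tailored step advice: intentions (6-month and
#' 1-month horizons), four attitude items, three self-efficacy items, social
#' support (partner/children/friends, support frequency and activity status),
#' pedometer familiarity, one benefit out of seven, and exactly two barriers
#' out of ten.
#'
#' @return A named list of character vectors, one per question facet.
#' @examples
#' answer_sets()$barriers
#' @export
answer_sets <- function() {
  list(
    yes_no            = c("yes", "no"),
    attitude_items    = c("healthy", "enjoyable", "good", "relaxing"),
    attitude_answers  = c("not_agree", "sometimes", "agree"),
    efficacy_items    = c("usual_week", "bad_days", "busy_days"),
    efficacy_answers  = c("sure_can", "think_can", "sure_cannot"),
    support_persons   = c("partner", "children", "friends"),
    support_frequency = c("never", "sometimes", "often", "not_applicable"),
    active_status     = c("yes", "no", "not_applicable"),
    benefits = c(
      "lose_weight", "feel_less_depressed", "feel_more_attractive",
      "better_physical_condition", "meet_new_people", "have_fun",
      "kick_of_competition"
    ),
    barriers = c(
      "lack_of_interest", "lack_of_time", "lack_of_self_discipline",
      "lack_of_social_support", "lack_of_pleasure", "external_factors",
      "lack_of_walking_partner", "lack_of_good_health",
      "activity_makes_me_tired", "having_an_injury"
    )
  )
}

#' The five stages of change
#'
#' Stage labels of the transtheoretical model in their canonical order, used
#' to tone the advice (impersonal for precontemplators through minimal
#' congratulation for maintainers).
#'
#' @return Character vector of length five.
#' @export
stages_of_change <- function() {
  c("precontemplation", "contemplation", "preparation", "action", "maintenance")
}

check_level <- function(x, set, name) {
  if (!is.character(x) || length(x) != 1L || !(x %in% set)) {
    stopf("`%s` must be one of: %s (got %s)", name,
          paste(set, collapse = ", "),
          if (length(x)) paste(x, collapse = ", ") else "<empty>")
  }
  x
}

check_named_levels <- function(x, items, set, name) {
  if (!is.character(x) || is.null(names(x)) || !setequal(names(x), items)) {
    stopf("`%s` must be a character vector named %s", name,
          paste(items, collapse = ", "))
  }
  for (it in items) check_level(unname(x[[it]]), set, paste0(name, "$", it))
  x[items]
}

#' Construct a tailoring questionnaire response
#'
#' Bundles one participant's answers to the diagnostic questionnaire together
#' with the researcher-computed average daily step count. All categorical
#' answers are validated against [answer_sets()]; `barriers` must contain
#' exactly two distinct entries.
#'
#' @param avg_daily_steps average daily steps over the valid pedometer week
#'   (steps/day, >= 0).
#' @param intent_6mo,intent_1mo `"yes"`/`"no"` intention to step more within
#'   6 months / 1 month. Both are required for participants below the
#'   10,000-step goal; may be `NULL` for participants at or above it.
#' @param attitudes named character vector over items
#'   `healthy, enjoyable, good, relaxing` with values
#'   `not_agree`/`sometimes`/`agree`.
#' @param self_efficacy named character vector over items
#'   `usual_week, bad_days, busy_days` with values
#'   `sure_can`/`think_can`/`sure_cannot`.
#' @param social_support list with elements `support` (named vector
#'   partner/children/friends -> `never`/`sometimes`/`often`/`not_applicable`)
#'   and `active` (same names -> `yes`/`no`/`not_applicable`).
#' @param pedometer_familiarity `"yes"`/`"no"`: familiar with pedometer use?
#' @param benefit one of the seven benefit options.
#' @param barriers exactly two distinct entries from the ten barrier options.
#' @param previous_avg_daily_steps optional steps/day from a previous advice
#'   request; triggers progress feedback when present.
#' @param months_meeting_goal optional number of months the participant has
#'   been at or above 10,000 steps/day (used to separate action from
#'   maintenance).
#' @return An object of class `tailoring_response`.
#' @examples
#' resp <- tailoring_response(
#'   avg_daily_steps = 6700, intent_6mo = "yes", intent_1mo = "yes",
#'   attitudes = c(healthy = "agree", enjoyable = "sometimes",
#'                 good = "agree", relaxing = "not_agree"),
#'   self_efficacy = c(usual_week = "think_can", bad_days = "sure_cannot",
#'                     busy_days = "think_can"),
#'   social_support = list(
#'     support = c(partner = "often", children = "not_applicable",
#'                 friends = "sometimes"),
#'     active = c(partner = "yes", children = "not_applicable",
#'                friends = "no")),
#'   pedometer_familiarity = "no",
#'   benefit = "better_physical_condition",
#'   barriers = c("lack_of_time", "external_factors"))
#' classify_stage(resp)
#' @export
tailoring_response <- function(avg_daily_steps,
                               intent_6mo = NULL,
                               intent_1mo = NULL,
                               attitudes,
                               self_efficacy,
                               social_support,
                               pedometer_familiarity,
                               benefit,
                               barriers,
                               previous_avg_daily_steps = NULL,
                               months_meeting_goal = NULL) {
  sets <- answer_sets()
  assert_scalar_number(avg_daily_steps, "avg_daily_steps", min = 0)
  if (!is.null(intent_6mo)) check_level(intent_6mo, sets$yes_no, "intent_6mo")
  if (!is.null(intent_1mo)) check_level(intent_1mo, sets$yes_no, "intent_1mo")
  attitudes <- check_named_levels(attitudes, sets$attitude_items,
                                  sets$attitude_answers, "attitudes")
  self_efficacy <- check_named_levels(self_efficacy, sets$efficacy_items,
                                      sets$efficacy_answers, "self_efficacy")
  if (!is.list(social_support) ||
      !all(c("support", "active") %in% names(social_support))) {
    stopf("`social_support` must be a list with elements `support` and `active`")
  }
  social_support$support <- check_named_levels(
    social_support$support, sets$support_persons, sets$support_frequency,
    "social_support$support")
  social_support$active <- check_named_levels(
    social_support$active, sets$support_persons, sets$active_status,
    "social_support$active")
  check_level(pedometer_familiarity, sets$yes_no, "pedometer_familiarity")
  check_level(benefit, sets$benefits, "benefit")
  if (!is.character(barriers) || length(barriers) != 2L ||
      anyDuplicated(barriers) || !all(barriers %in% sets$barriers)) {
    stopf("`barriers` must be exactly 2 distinct entries from the barrier list")
  }
  if (!is.null(previous_avg_daily_steps)) {
    assert_scalar_number(previous_avg_daily_steps, "previous_avg_daily_steps",
                         min = 0)
  }
  if (!is.null(months_meeting_goal)) {
    assert_scalar_number(months_meeting_goal, "months_meeting_goal", min = 0)
  }
  structure(
    list(
      avg_daily_steps = avg_daily_steps,
      intent_6mo = intent_6mo,
      intent_1mo = intent_1mo,
      attitudes = attitudes,
      self_efficacy = self_efficacy,
      social_support = social_support[c("support", "active")],
      pedometer_familiarity = pedometer_familiarity,
      benefit = benefit,
      barriers = barriers,
      previous_avg_daily_steps = previous_avg_daily_steps,
      months_meeting_goal = months_meeting_goal
    ),
    class = "tailoring_response"
  )
}

#' @export
print.tailoring_response <- function(x, ...) {
  cat("<tailoring_response>\n")
  cat("  avg daily steps:", x$avg_daily_steps, "\n")
  cat("  stage:", tryCatch(classify_stage(x), error = function(e) "<unclassifiable>"), "\n")
  cat("  barriers:", paste(x$barriers, collapse = ", "), "\n")
  invisible(x)
}
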