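test_that("stage classification follows the staging rules and partitions the input space", {
  expect_identical(classify_stage(make_response(avg_daily_steps = 6000,
                                                intent_6mo = "no",
                                                intent_1mo = "no")),
                   "precontemplation")
  expect_identical(classify_stage(make_response(avg_daily_steps = 6000,
                                                intent_6mo = "yes",
                                                intent_1mo = "no")),
                   "contemplation")
  expect_identical(classify_stage(make_response(avg_daily_steps = 6000,
                                                intent_6mo = "yes",
                                                intent_1mo = "yes")),
                   "preparation")
  expect_identical(classify_stage(make_response(avg_daily_steps = 11000,
                                                months_meeting_goal = 8)),
                   "maintenance")
  expect_identical(classify_stage(make_response(avg_daily_steps = 11000,
                                                months_meeting_goal = 2)),
                   "action")
  # unknown duration at goal defaults to action
  expect_identical(classify_stage(make_response(avg_daily_steps = 10000)),
                   "action")
  # the more proximal intention dominates
  expect_identical(classify_stage(make_response(avg_daily_steps = 6000,
                                                intent_6mo = "no",
                                                intent_1mo = "yes")),
                   "preparation")

  # exactly one stage fires for every legal (steps, intent, months) cell
  grid <- expand.grid(steps = c(0, 5000, 9999, 10000, 15000),
                      i6 = c("yes", "no"), i1 = c("yes", "no"),
                      months = c(NA, 0, 5, 6, 24), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    stage <- classify_stage(make_response(
      avg_daily_steps = g$steps, intent_6mo = g$i6, intent_1mo = g$i1,
      months_meeting_goal = if (is.na(g$months)) NULL else g$months))
    expect_length(stage, 1)
    expect_true(stage %in% stages_of_change())
  }
})

test_that("missing intention answers for a below-goal participant are an error naming the field", {
  expect_error(classify_stage(make_response(avg_daily_steps = 6000,
                                            intent_6mo = NULL,
                                            intent_1mo = NULL)),
               "intent_1mo")
  expect_error(classify_stage(make_response(avg_daily_steps = 6000,
                                            intent_6mo = NULL,
                                            intent_1mo = "no")),
               "intent_6mo")
})

test_that("step schedules increase by the chosen increment and cap at 10,000", {
  expect_identical(generate_schedule(6700, 500)$weekly_goals,
                   c(7200L, 7700L, 8200L, 8700L, 9200L, 9700L, 10000L))
  expect_identical(generate_schedule(10000, 1000)$weekly_goals, integer(0))
  expect_identical(generate_schedule(9900, 1000)$weekly_goals, 10000L)
  expect_error(generate_schedule(-1, 500), "baseline")
  expect_error(generate_schedule(5000, 750), "increment")
})

test_that("schedule length, monotonicity and terminal goal hold on a grid of baselines", {
  for (inc in c(500, 1000)) {
    for (b in seq(0, 9900, by = 300)) {
      g <- generate_schedule(b, inc)$weekly_goals
      expect_length(g, ceiling((10000 - b) / inc))
      expect_true(all(diff(g) >= 0))
      expect_identical(g[length(g)], 10000L)
      expect_true(all(g <= 10000L))
    }
  }
})

test_that("determinant feedback selects the keyed messages", {
  bank <- load_message_bank()
  expect_identical(
    select_determinant_feedback("knowledge", "no", "preparation", bank),
    "pedometer_primer")
  expect_identical(
    select_determinant_feedback("knowledge", "yes", "preparation", bank),
    character(0))
  ids <- select_determinant_feedback(
    "barriers", c("external_factors", "lack_of_time"), "preparation", bank)
  expect_length(ids, 2)
  txt <- steptailor:::render_message(bank, ids, list(steps = "1", goal = "2"))
  expect_true(any(grepl("does not have to be expensive", txt)))
  expect_error(
    select_determinant_feedback("benefits", "win_the_lottery", "action", bank),
    "win_the_lottery")
})

test_that("advice documents have three parts, stage-matched tone, and resolve all messages", {
  bank <- load_message_bank()
  pre <- compose_advice(make_response(avg_daily_steps = 6000,
                                      intent_6mo = "no", intent_1mo = "no"),
                        bank)
  expect_identical(pre$stage, "precontemplation")
  expect_true(grepl("health", pre$introduction, ignore.case = TRUE))
  expect_false(grepl("set a concrete goal", pre$introduction))
  expect_null(pre$progress_note)

  maint <- compose_advice(make_response(avg_daily_steps = 12000,
                                        months_meeting_goal = 12), bank)
  expect_identical(maint$stage, "maintenance")
  expect_length(maint$personal_feedback$schedule$weekly_goals, 0)
  expect_true(grepl("Congratulations", maint$introduction))

  doc <- compose_advice(make_response(), bank)
  expect_named(doc, c("introduction", "personal_feedback", "recommendations",
                      "stage", "progress_note", "determinant_messages"))
  all_ids <- unlist(doc$determinant_messages)
  expect_true(all(all_ids %in% bank$id))
  md <- advice_markdown(doc)
  expect_match(md, "## Introduction")
  expect_match(md, "## Recommendations")
  expect_match(advice_html(doc), "<h2>Recommendations</h2>", fixed = TRUE)
})

test_that("composition is deterministic and the progress note appears iff a previous level exists", {
  d1 <- compose_advice(make_response(previous_avg_daily_steps = 6000))
  d2 <- compose_advice(make_response(previous_avg_daily_steps = 6000))
  expect_identical(d1, d2)
  expect_identical(advice_markdown(d1), advice_markdown(d2))
  expect_false(is.null(d1$progress_note))
  expect_null(compose_advice(make_response())$progress_note)
})

test_that("progress feedback signs deltas and picks the matching variant", {
  up <- progress_feedback(6697, 7753)
  expect_identical(up$delta, 1056)
  expect_identical(up$variant, "improved")
  expect_match(up$text, "1,056")
  flat <- progress_feedback(8000, 8000)
  expect_identical(flat$delta, 0)
  expect_identical(flat$variant, "unchanged")
  down <- progress_feedback(9000, 8500)
  expect_identical(down$delta, -500)
  expect_identical(down$variant, "declined")
})

test_that("the questionnaire constructor enforces the legal answer sets", {
  expect_error(make_response(barriers = c("lack_of_time", "lack_of_time")),
               "distinct")
  expect_error(make_response(barriers = "lack_of_time"), "exactly 2")
  expect_error(make_response(benefit = "world_peace"), "benefit")
  expect_error(make_response(attitudes = c(healthy = "agree")), "attitudes")
  expect_error(make_response(avg_daily_steps = -5), "avg_daily_steps")
})
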