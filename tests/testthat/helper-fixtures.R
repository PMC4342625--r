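# Shared fixtures built in code.

# a valid tailoring response with overridable fields
make_response <- function(...) {
  defaults <- list(
    avg_daily_steps = 6700,
    intent_6mo = "yes", intent_1mo = "yes",
    attitudes = c(healthy = "agree", enjoyable = "sometimes",
                  good = "agree", relaxing = "not_agree"),
    self_efficacy = c(usual_week = "think_can", bad_days = "sure_cannot",
                      busy_days = "think_can"),
    social_support = list(
      support = c(partner = "often", children = "not_applicable",
                  friends = "sometimes"),
      active = c(partner = "yes", children = "not_applicable",
                 friends = "no")),
    pedometer_familiarity = "no",
    benefit = "better_physical_condition",
    barriers = c("lack_of_time", "external_factors")
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(tailoring_response, args)
}

# a week of pedometer records (Mon 2024-03-04 .. Sun 2024-03-10)
make_week <- function(steps = rep(8000, 7), wear = rep(12, 7),
                      start = as.Date("2024-03-04")) {
  step_series(start + seq_along(steps) - 1, steps, wear)
}

# hand-built long cohort: one row per participant x wave, normal outcomes
make_null_cohort <- function(n_per_arm = 40, seed = 1, mean = 7000, sd = 2000,
                             arm_shift_t1 = 0) {
  set.seed(seed)
  n <- 2 * n_per_arm
  arm <- rep(c("IG", "CG"), each = n_per_arm)
  id <- sprintf("N%03d", seq_len(n))
  rows <- lapply(c("T0", "T1", "T2"), function(w) {
    shift <- if (w != "T0") ifelse(arm == "IG", arm_shift_t1, 0) else 0
    tibble::tibble(
      participant_id = id,
      cluster = rep(c("c1", "c2", "c3", "c4"), length.out = n),
      cluster_type = rep(c("school", "commercial", "nonprofit", "school"),
                         length.out = n),
      arm = arm, wave = w,
      steps = rnorm(n, mean + shift, sd),
      sitting = rnorm(n, 480, 150),
      walking = rexp(n, 1 / 20), moderate = rexp(n, 1 / 15),
      vigorous = rexp(n, 1 / 8),
      observed = TRUE)
  })
  dplyr::bind_rows(rows)
}

# closed-form Pearson chi-square oracle, independent of chi_square_2x2
chisq_oracle <- function(m) {
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - expected)^2 / expected)
}
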