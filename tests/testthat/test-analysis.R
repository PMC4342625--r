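test_that("the at-risk filter partitions on the strict 10,000-step baseline threshold", {
  co <- make_null_cohort(n_per_arm = 20, seed = 1)
  co$steps[co$wave == "T0"] <- c(9999, 10000, rep(c(6000, 12000), 19))
  parts <- at_risk_filter(co)
  ids_risk <- unique(parts$at_risk$participant_id)
  ids_rest <- unique(parts$not_at_risk$participant_id)
  expect_length(intersect(ids_risk, ids_rest), 0)
  expect_setequal(c(ids_risk, ids_rest), unique(co$participant_id))
  t0 <- co[co$wave == "T0", ]
  expect_true(t0$participant_id[t0$steps == 9999] %in% ids_risk)
  expect_true(t0$participant_id[t0$steps == 10000][1] %in% ids_rest)
})

test_that("the 2x2 chi-square matches the closed form on 1,000 random tables", {
  tab <- chi_square_2x2(46, 91, 30, 107)
  expect_equal(round(tab$statistic, 3), 4.661)
  expect_identical(tab$df, 1L)
  expect_lt(tab$p_value, 0.05)

  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
  expect_error(chi_square_2x2(-1, 2, 3, 4), ">= 0")

  set.seed(99)
  for (i in 1:1000) {
    cells <- rpois(4, lambda = sample(5:60, 1)) + 1
    got <- chi_square_2x2(cells[1], cells[2], cells[3], cells[4])$statistic
    want <- chisq_oracle(matrix(cells, 2, byrow = TRUE))
    expect_lt(abs(got - want), 1e-9)
  }
})

test_that("baseline comparison flags a configured sitting-time shift and skips constants", {
  cfg <- default_sim_config("total")   # sitting 526.7 vs 465.2 min/day at T0
  hits <- vapply(1:10, function(s) {
    co <- simulate_cohort(cfg, s)
    bl <- baseline_comparison(co)
    bl$significant[bl$characteristic == "sitting"]
  }, logical(1))
  expect_gt(mean(hits), 0.5)
  co <- simulate_cohort(cfg, 1)
  expect_true("sitting" %in% attr(baseline_comparison(co), "covariates") ||
                !baseline_comparison(co)$significant[2])

  co$steps <- 1
  expect_warning(baseline_comparison(co, continuous = "steps"), "constant")
})

test_that("identical arms are flagged at roughly the nominal rate", {
  p_vals <- vapply(1:60, function(s) {
    co <- make_null_cohort(n_per_arm = 30, seed = s)
    bl <- baseline_comparison(co, continuous = "steps")
    bl$p[bl$characteristic == "steps"]
  }, numeric(1))
  # 60 null draws: rejections at 5% should be rare but possible
  expect_lt(mean(p_vals <= 0.05), 0.2)
  expect_gt(mean(p_vals <= 0.5), 0.2)   # p roughly uniform, not degenerate
})

test_that("the worksite variance LRT is near zero without cluster structure and grows with it", {
  cfg <- default_sim_config("at_risk")
  stats0 <- c(); stats_mid <- c(); stats_big <- c()
  for (s in 1:5) {
    cfg$cluster_sd <- 0
    stats0[s] <- cluster_variance_test(simulate_cohort(cfg, s))$statistic
    cfg$cluster_sd <- 600
    stats_mid[s] <- cluster_variance_test(simulate_cohort(cfg, s))$statistic
    cfg$cluster_sd <- 1500
    stats_big[s] <- cluster_variance_test(simulate_cohort(cfg, s))$statistic
  }
  expect_true(all(stats0 >= 0))
  expect_lt(mean(stats0), 2)
  expect_lt(mean(stats0), mean(stats_mid))
  expect_lt(mean(stats_mid), mean(stats_big))
  expect_gt(mean(stats_big > 3.84), 0.5)

  one <- make_null_cohort(10, 1)
  one$cluster <- "only"
  expect_error(cluster_variance_test(one), "2 clusters")
})

test_that("the change-score ANCOVA equals the mixed-ANOVA interaction F on balanced data", {
  co <- make_null_cohort(n_per_arm = 25, seed = 3, arm_shift_t1 = 800)
  row <- rm_ancova(co, "steps", c("T0", "T1"), transform = "none")

  long <- co[co$wave %in% c("T0", "T1"), ]
  long$wave <- factor(long$wave); long$arm <- factor(long$arm)
  fit <- stats::aov(steps ~ arm * wave + Error(participant_id / wave),
                    data = long)
  tab <- summary(fit)[["Error: participant_id:wave"]][[1]]
  f_oracle <- tab["arm:wave", "F value"]
  p_oracle <- tab["arm:wave", "Pr(>F)"]
  expect_equal(row$F_stat, f_oracle, tolerance = 1e-8)
  expect_equal(row$p, p_oracle, tolerance = 1e-8)
  expect_identical(row$df2, as.integer(tab["Residuals", "Df"]))
})

test_that("ANCOVA degrees of freedom follow n - 2 - n_covariates", {
  co <- make_null_cohort(n_per_arm = 30, seed = 5)
  plain <- rm_ancova(co, "steps", c("T0", "T1"), transform = "none")
  expect_identical(plain$df2, 60L - 2L)
  adj <- rm_ancova(co, "steps", c("T0", "T1"), covariates = "sitting",
                   transform = "none")
  expect_identical(adj$df2, 60L - 3L)
  expect_identical(adj$df1, 1L)
  tiny <- co[co$participant_id %in% unique(co$participant_id)[1:3], ]
  expect_error(rm_ancova(tiny, "steps", c("T0", "T1")), "fewer than 2")
})

test_that("a shared time effect without interaction stays non-significant at roughly 1 - alpha", {
  p_vals <- vapply(1:60, function(s) {
    co <- make_null_cohort(n_per_arm = 30, seed = 100 + s)
    co$steps[co$wave == "T1"] <- co$steps[co$wave == "T1"] + 1000  # both arms
    rm_ancova(co, "steps", c("T0", "T1"), transform = "none")$p
  }, numeric(1))
  expect_lt(mean(p_vals <= 0.05), 0.2)
})

test_that("skewed outcomes are tested on the log scale but described on the raw scale", {
  cfg <- default_sim_config("at_risk")
  co <- simulate_cohort(cfg, 9)
  row <- rm_ancova(co, "walking", c("T0", "T1"))
  expect_true(row$transformed)
  # raw-scale descriptives: means near the configured lognormal means
  expect_gt(row$mean_IG_w2, row$mean_IG_w1)
  expect_lt(abs(row$mean_IG_w1 - 12.49), 15)
})

test_that("guideline attainment reports rounded percentages with raw fractions", {
  co <- make_null_cohort(n_per_arm = 55, seed = 2)
  t2_ig <- which(co$wave == "T2" & co$arm == "IG")
  co$steps[t2_ig] <- c(rep(12000, 36), rep(5000, 19))
  res <- guideline_attainment(co, "T2", "IG")
  expect_identical(res$percentage, 65)
  expect_identical(res$numerator, 36L)
  expect_identical(res$denominator, 55L)

  t1_ig <- which(co$wave == "T1" & co$arm == "IG")
  co$steps[t1_ig] <- c(rep(10000, 16), rep(3000, 37), 1, 1)
  co$observed[t1_ig[54:55]] <- FALSE
  res2 <- guideline_attainment(co, "T1", "IG")
  expect_identical(res2$percentage, 30)
  expect_identical(res2$numerator, 16L)
  expect_identical(res2$denominator, 53L)

  co$steps[co$wave == "T0" & co$arm == "CG"] <- 2000
  expect_identical(guideline_attainment(co, "T0", "CG")$percentage, 0)
  empty <- co[co$arm == "IG", ]
  expect_error(guideline_attainment(empty, "T0", "CG"), "no observed")
})

test_that("change summaries difference the wave means per arm", {
  row <- tibble::tibble(outcome = "steps", contrast = "T0-T1",
                        n_IG = 65L, n_CG = 74L,
                        mean_IG_w1 = 6697.34, sd_IG_w1 = 1864.33,
                        mean_IG_w2 = 7753.18, sd_IG_w2 = 3196.10,
                        mean_CG_w1 = 6898.16, sd_CG_w1 = 1979.35,
                        mean_CG_w2 = 6640.43, sd_CG_w2 = 2751.43,
                        F_stat = 11.977, df1 = 1L, df2 = 136L, p = 0.001,
                        transformed = TRUE, borderline = FALSE)
  ch <- change_summary(row)
  expect_equal(ch$change[ch$arm == "IG"], 1056)
  expect_equal(ch$change[ch$arm == "CG"], -258)

  row$outcome <- "walking"
  row$mean_IG_w2 <- row$mean_IG_w1
  row$mean_CG_w2 <- row$mean_CG_w1
  ch0 <- change_summary(row)
  expect_equal(ch0$change, c(0, 0))
})

test_that("dropout analysis reproduces the arm chi-square from completion counts", {
  cfg <- default_sim_config("total")
  co <- simulate_cohort(cfg, 6)
  # force completion counts: 91/137 IG and 107/137 CG completers at T2
  ids_ig <- unique(co$participant_id[co$arm == "IG"])
  ids_cg <- unique(co$participant_id[co$arm == "CG"])
  drop_ids <- c(ids_ig[1:46], ids_cg[1:30])
  co$observed[co$wave == "T2" & co$participant_id %in% drop_ids] <- FALSE
  out <- dropout_analysis(co)
  arm_row <- out[out$characteristic == "arm", ]
  expect_equal(round(arm_row$statistic, 3), 4.661)
  expect_identical(arm_row$df, 1)
  ct_row <- out[out$characteristic == "cluster_type", ]
  expect_identical(as.integer(ct_row$df), 2L)
  expect_true(all(c("steps", "sitting") %in% out$characteristic))

  full <- simulate_cohort(cfg, 6)
  expect_warning(dropout_analysis(full), "no variation")
})

test_that("the full pipeline is deterministic on a fixed cohort", {
  cfg <- default_sim_config("at_risk")
  co <- apply_dropout(simulate_cohort(cfg, 11), cfg, 11)
  t1 <- effect_table(co, outcomes = c("steps", "walking"),
                     contrasts = list(c("T0", "T1")))
  t2 <- effect_table(co, outcomes = c("steps", "walking"),
                     contrasts = list(c("T0", "T1")))
  expect_identical(t1, t2)
})
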