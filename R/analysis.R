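# The trial's statistical pipeline: baseline comparison, dropout analysis,
# cluster variance check, repeated-measures ANCOVA per outcome/contrast,
# at-risk subsetting, and guideline attainment.

OUTCOME_VARS <- c("steps", "sitting", "walking", "moderate", "vigorous",
                  "total_pa")

# add the summed self-report total where absent
with_total_pa <- function(cohort) {
  if (!"total_pa" %in% names(cohort)) {
    cohort$total_pa <- cohort$walking + cohort$moderate + cohort$vigorous
  }
  cohort
}

#' Percentage with explicit rounding
#'
#' @param numerator,denominator counts.
#' @param digits decimal places (half-away-from-zero rounding).
#' @return `100 * numerator / denominator`, rounded.
#' @examples
#' proportion_pct(274, 1817)      # 15.1
#' proportion_pct(190, 274)       # 69.3
#' @export
proportion_pct <- function(numerator, denominator, digits = 1) {
  if (denominator <= 0) stopf("empty denominator")
  round_half_up(100 * numerator / denominator, digits)
}

#' Split a cohort into at-risk and not-at-risk participants
#'
#' The at-risk sample holds participants below 10,000 steps/day at baseline
#' (strictly); the two subsets partition the cohort.
#'
#' @param cohort long-format cohort with a `T0` wave and `steps`.
#' @param goal threshold in steps/day (default 10,000).
#' @return List with tibbles `at_risk` and `not_at_risk`.
#' @examples
#' \dontrun{at_risk_filter(cohort)$at_risk}
#' @export
at_risk_filter <- function(cohort, goal = 10000) {
  t0 <- cohort[cohort$wave == "T0", c("participant_id", "steps")]
  if (nrow(t0) == 0) stopf("cohort has no baseline (T0) wave")
  risk_ids <- t0$participant_id[!is.na(t0$steps) & t0$steps < goal]
  list(at_risk = cohort[cohort$participant_id %in% risk_ids, ],
       not_at_risk = cohort[!cohort$participant_id %in% risk_ids, ])
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected (no continuity correction), two-tailed, df = 1. The table is
#' `rbind(c(a, b), c(c, d))`.
#'
#' @param a,b,c,d nonnegative cell counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_2x2(46, 91, 30, 107)$statistic  # 4.661
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stopf("counts must be >= 0")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stopf("degenerate table: zero margin")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = 1L,
       p_value = unname(ht$p.value))
}

#' Baseline comparison between arms
#'
#' Compares baseline (T0) characteristics between intervention and control:
#' independent-sample t tests for quantitative variables, chi-square tests
#' for categorical ones. Characteristics significant at `alpha` form the
#' covariate set for the downstream ANCOVAs; p values in (0.05, 0.10] are
#' flagged borderline. Constant (or all-missing) characteristics are skipped
#' with a warning.
#'
#' @param cohort long-format cohort.
#' @param continuous names of quantitative columns to compare at T0.
#' @param categorical names of categorical columns to compare at T0.
#' @param alpha significance level (default 0.05).
#' @return Tibble with one row per characteristic (`statistic`, `df`, `p`,
#'   `test`, `significant`, `borderline`); attribute `covariates` holds the
#'   significant quantitative characteristics.
#' @export
baseline_comparison <- function(cohort,
                                continuous = intersect(OUTCOME_VARS, names(with_total_pa(cohort))),
                                categorical = character(0),
                                alpha = 0.05) {
  cohort <- with_total_pa(cohort)
  t0 <- cohort[cohort$wave == "T0" & cohort$observed, ]
  rows <- list()
  for (v in continuous) {
    x <- t0[[v]][t0$arm == "IG"]
    y <- t0[[v]][t0$arm == "CG"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2 || stats::sd(c(x, y)) == 0) {
      warning(sprintf("skipping constant or near-empty characteristic `%s`", v))
      next
    }
    ht <- stats::t.test(x, y, var.equal = TRUE)
    rows[[v]] <- tibble::tibble(
      characteristic = v, test = "t",
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value)
  }
  for (v in categorical) {
    tab <- table(t0$arm, t0[[v]])
    if (any(dim(tab) < 2)) {
      warning(sprintf("skipping constant characteristic `%s`", v))
      next
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[v]] <- tibble::tibble(
      characteristic = v, test = "chi-square",
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value)
  }
  empty <- tibble::tibble(characteristic = character(0), test = character(0),
                          statistic = numeric(0), df = numeric(0),
                          p = numeric(0))
  out <- dplyr::bind_rows(c(list(empty), rows))
  out$significant <- out$p <= alpha
  out$borderline <- out$p > alpha & out$p <= 0.10
  attr(out, "covariates") <-
    out$characteristic[out$significant & out$test == "t"]
  out
}

#' Likelihood-ratio test for worksite-level variance
#'
#' Compares a participant random-intercept model with and without an
#' additional worksite (cluster) random intercept, by maximum likelihood.
#' The statistic is `2 * (logLik_full - logLik_reduced)`, floored at 0
#' (boundary convention), referred to chi-square with df = 1.
#'
#' @param cohort long-format cohort (observed rows are used).
#' @param outcome outcome column (default `"steps"`).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
cluster_variance_test <- function(cohort, outcome = "steps") {
  cohort <- with_total_pa(cohort)
  d <- cohort[cohort$observed & !is.na(cohort[[outcome]]), ]
  if (length(unique(d$cluster)) < 2) stopf("need at least 2 clusters")
  d$y <- d[[outcome]]
  m1 <- suppressMessages(suppressWarnings(lme4::lmer(
    y ~ wave * arm + (1 | participant_id) + (1 | cluster),
    data = d, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))))
  m0 <- suppressMessages(suppressWarnings(lme4::lmer(
    y ~ wave * arm + (1 | participant_id),
    data = d, REML = FALSE)))
  stat <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                      as.numeric(stats::logLik(m0))))
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# wide available-case data for one outcome and wave pair
contrast_data <- function(cohort, outcome, waves, covariates) {
  cohort <- with_total_pa(cohort)
  keep <- cohort$wave %in% c(waves, "T0") & cohort$observed
  d <- cohort[keep, ]
  get_wave <- function(w, var) {
    sub <- d[d$wave == w, c("participant_id", var)]
    names(sub)[2] <- paste0(var, "_", w)
    sub
  }
  wide <- merge(get_wave(waves[1], outcome), get_wave(waves[2], outcome),
                by = "participant_id")
  for (cv in covariates) {
    wide <- merge(wide, get_wave("T0", cv), by = "participant_id")
  }
  info <- cohort[match(wide$participant_id, cohort$participant_id),
                 c("participant_id", "arm", "cluster")]
  wide <- merge(wide, info, by = "participant_id")
  stats::na.omit(wide)
}

#' Repeated-measures ANCOVA for one outcome and wave pair
#'
#' Tests the time x condition interaction between two waves, adjusting for
#' baseline covariates, on the available cases (participants observed at both
#' waves with complete covariates). The interaction is parameterized as the
#' arm effect on the within-participant change score -- for balanced two-wave
#' data this is algebraically the mixed-ANOVA time x group F with
#' F(1, n - 2 - n_covariates). When the pooled outcome fails the normality
#' screen of [log_transform_if_skewed()], the test runs on the
#' `log(x + 1)` scale; descriptive means and SDs are always reported on the
#' raw scale.
#'
#' @param cohort long-format cohort.
#' @param outcome one of `steps`, `sitting`, `walking`, `moderate`,
#'   `vigorous`, `total_pa`.
#' @param waves length-2 wave pair, e.g. `c("T0", "T1")`.
#' @param covariates baseline covariate columns (e.g. `"sitting"`).
#' @param transform `"auto"` (normality screen decides), `"log"`, or
#'   `"none"`.
#' @return One-row tibble: per-arm n, raw means/SDs at both waves, `F_stat`,
#'   `df1`, `df2`, `p`, `transformed`, and the contrast label.
#' @examples
#' \dontrun{rm_ancova(cohort, "steps", c("T0", "T1"), covariates = "sitting")}
#' @export
rm_ancova <- function(cohort, outcome, waves = c("T0", "T1"),
                      covariates = character(0), transform = "auto") {
  stopifnot(length(waves) == 2)
  covariates <- setdiff(covariates, outcome)
  wide <- contrast_data(cohort, outcome, waves, covariates)
  y1 <- wide[[paste0(outcome, "_", waves[1])]]
  y2 <- wide[[paste0(outcome, "_", waves[2])]]
  if (sum(wide$arm == "IG") < 2 || sum(wide$arm == "CG") < 2) {
    stopf("fewer than 2 analyzable participants per arm for %s %s-%s",
          outcome, waves[1], waves[2])
  }
  do_log <- switch(transform,
    auto = log_transform_if_skewed(c(y1, y2))$decision == "transformed",
    log = TRUE,
    none = FALSE,
    stopf("`transform` must be auto, log or none"))
  a1 <- if (do_log) log(y1 + 1) else y1
  a2 <- if (do_log) log(y2 + 1) else y2
  wide$change <- a2 - a1
  wide$arm <- factor(wide$arm, levels = c("CG", "IG"))
  cov_terms <- if (length(covariates)) paste0(covariates, "_T0") else NULL
  rhs <- paste(c("arm", cov_terms), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("change ~", rhs)), data = wide)
  sm <- summary(fit)
  t_arm <- sm$coefficients["armIG", "t value"]
  df2 <- fit$df.residual
  f <- t_arm^2
  p <- 2 * stats::pt(abs(t_arm), df2, lower.tail = FALSE)

  per_arm <- function(arm, v) c(mean = mean(v[wide$arm == arm]),
                                sd = stats::sd(v[wide$arm == arm]))
  ig1 <- per_arm("IG", y1); ig2 <- per_arm("IG", y2)
  cg1 <- per_arm("CG", y1); cg2 <- per_arm("CG", y2)
  tibble::tibble(
    outcome = outcome,
    contrast = paste(waves, collapse = "-"),
    n_IG = sum(wide$arm == "IG"), n_CG = sum(wide$arm == "CG"),
    mean_IG_w1 = ig1[["mean"]], sd_IG_w1 = ig1[["sd"]],
    mean_IG_w2 = ig2[["mean"]], sd_IG_w2 = ig2[["sd"]],
    mean_CG_w1 = cg1[["mean"]], sd_CG_w1 = cg1[["sd"]],
    mean_CG_w2 = cg2[["mean"]], sd_CG_w2 = cg2[["sd"]],
    F_stat = f, df1 = 1L, df2 = df2, p = p,
    transformed = do_log,
    borderline = p > 0.05 & p <= 0.10
  )
}

#' Effect table over outcomes and contrasts
#'
#' Runs [rm_ancova()] for every outcome x wave-pair combination, available
#' case per cell, mirroring the trial's effect tables.
#'
#' @param cohort long-format cohort.
#' @param outcomes outcome columns to analyze.
#' @param contrasts list of wave pairs.
#' @param covariates baseline covariates passed to every ANCOVA.
#' @return Tibble with one row per outcome x contrast.
#' @export
effect_table <- function(cohort, outcomes = OUTCOME_VARS,
                         contrasts = list(c("T0", "T1"), c("T1", "T2"),
                                          c("T0", "T2")),
                         covariates = "sitting") {
  rows <- list()
  for (oc in outcomes) {
    for (ct in contrasts) {
      rows[[paste(oc, paste(ct, collapse = "-"))]] <-
        rm_ancova(cohort, oc, ct, covariates = covariates)
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-arm mean change for an effect row
#'
#' @param effect_row a one-row result of [rm_ancova()].
#' @param round_steps round changes to whole steps (default: when the row's
#'   outcome is `steps`).
#' @return Tibble with per-arm `change` (wave-2 mean minus wave-1 mean).
#' @examples
#' \dontrun{change_summary(rm_ancova(cohort, "steps"))}
#' @export
change_summary <- function(effect_row,
                           round_steps = effect_row$outcome == "steps") {
  stopifnot(nrow(effect_row) == 1)
  ch <- c(IG = effect_row$mean_IG_w2 - effect_row$mean_IG_w1,
          CG = effect_row$mean_CG_w2 - effect_row$mean_CG_w1)
  if (isTRUE(round_steps)) ch <- round_half_up(ch)
  tibble::tibble(arm = names(ch), change = unname(ch),
                 outcome = effect_row$outcome, contrast = effect_row$contrast)
}

#' Percentage of participants meeting the 10,000-step guideline
#'
#' @param cohort long-format cohort.
#' @param wave wave label.
#' @param arm arm label (`"IG"` or `"CG"`).
#' @param goal steps/day threshold (default 10,000; attainment is `>= goal`).
#' @return List with `percentage` (integer percent, half-away-from-zero),
#'   `numerator`, `denominator`.
#' @examples
#' \dontrun{guideline_attainment(cohort, "T2", "IG")}
#' @export
guideline_attainment <- function(cohort, wave, arm, goal = 10000) {
  d <- cohort[cohort$wave == wave & cohort$arm == arm & cohort$observed &
                !is.na(cohort$steps), ]
  if (nrow(d) == 0) stopf("no observed step data for %s at %s", arm, wave)
  num <- sum(d$steps >= goal)
  den <- nrow(d)
  list(percentage = round_half_up(100 * num / den), numerator = num,
       denominator = den)
}

#' Completer-versus-dropout analysis
#'
#' Completion is complete data at T2. Tests: arm vs completion (2x2
#' chi-square, df = 1), cluster type vs completion (2x3 chi-square, df = 2),
#' and independent-sample t tests on the baseline values of the continuous
#' outcomes. With no dropout the tests are skipped with a warning.
#'
#' @param cohort long-format cohort with dropout applied.
#' @return Tibble with one row per test (`characteristic`, `test`,
#'   `statistic`, `df`, `p`).
#' @export
dropout_analysis <- function(cohort) {
  cohort <- with_total_pa(cohort)
  t2 <- cohort[cohort$wave == "T2", ]
  completer <- t2$observed
  names(completer) <- t2$participant_id
  t0 <- cohort[cohort$wave == "T0", ]
  t0$completer <- completer[t0$participant_id]
  if (all(t0$completer) || !any(t0$completer)) {
    warning("no variation in completion status; dropout tests skipped")
    return(tibble::tibble(characteristic = character(0), test = character(0),
                          statistic = numeric(0), df = numeric(0),
                          p = numeric(0)))
  }
  rows <- list()
  tab <- table(t0$arm, t0$completer)
  ct <- chi_square_2x2(tab["IG", "FALSE"], tab["IG", "TRUE"],
                       tab["CG", "FALSE"], tab["CG", "TRUE"])
  rows$arm <- tibble::tibble(characteristic = "arm", test = "chi-square",
                             statistic = ct$statistic, df = ct$df,
                             p = ct$p_value)
  type_tab <- table(t0$cluster_type, t0$completer)
  if (nrow(type_tab) > 1) {
    ht <- suppressWarnings(stats::chisq.test(type_tab, correct = FALSE))
    rows$cluster_type <- tibble::tibble(
      characteristic = "cluster_type", test = "chi-square",
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value)
  }
  for (v in intersect(OUTCOME_VARS, names(t0))) {
    x <- t0[[v]][t0$completer]
    y <- t0[[v]][!t0$completer]
    if (length(x) < 2 || length(y) < 2 || stats::sd(c(x, y), na.rm = TRUE) == 0) next
    ht <- stats::t.test(x, y, var.equal = TRUE)
    rows[[v]] <- tibble::tibble(characteristic = v, test = "t",
                                statistic = unname(ht$statistic),
                                df = unname(ht$parameter), p = ht$p.value)
  }
  dplyr::bind_rows(rows)
}
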