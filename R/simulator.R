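# Synthetic cluster-RCT generator: 8 worksite clusters, 2 arms, 3 waves,
# pedometer and self-report outcomes, monotone differential dropout.
# Defaults reproduce the reference trial's published arm x wave means/SDs,
# group sizes and retention.

# outcome, arm, wave, mean, sd, dist rows for the two default samples.
# Steps and sitting are drawn normal (truncated/floored); the self-report
# activity domains are drawn moment-matched lognormal to reproduce their
# positive skew.
outcome_defaults <- function(sample) {
  row <- function(outcome, arm, m, s, dist) {
    data.frame(outcome = outcome, arm = arm, wave = c("T0", "T1", "T2"),
               mean = m, sd = s, dist = dist)
  }
  if (sample == "at_risk") {
    rbind(
      row("steps", "IG", c(6697.34, 7753.18, 8019.24),
          c(1864.33, 3196.10, 3997.34), "normal"),
      row("steps", "CG", c(6898.16, 6640.43, 7308.22),
          c(1979.35, 2751.43, 3803.62), "normal"),
      row("sitting", "IG", c(534.07, 541.67, 501.78),
          c(163.11, 142.90, 152.09), "normal"),
      row("sitting", "CG", c(497.46, 498.46, 460.25),
          c(193.33, 193.72, 201.61), "normal"),
      row("walking", "IG", c(12.49, 39.48, 31.45),
          c(24.17, 113.45, 56.88), "lognormal"),
      row("walking", "CG", c(12.56, 19.55, 37.87),
          c(16.60, 22.35, 50.84), "lognormal"),
      row("moderate", "IG", c(16.94, 21.62, 30.38),
          c(24.05, 34.70, 36.23), "lognormal"),
      row("moderate", "CG", c(19.45, 9.56, 33.95),
          c(37.70, 11.27, 55.84), "lognormal"),
      row("vigorous", "IG", c(6.88, 6.67, 10.98),
          c(13.57, 12.70, 20.89), "lognormal"),
      row("vigorous", "CG", c(5.87, 3.68, 6.03),
          c(18.68, 8.13, 14.02), "lognormal")
    )
  } else {
    rbind(
      row("steps", "IG", c(8759.98, 9235.48, 9483.86),
          c(3771.32, 4281.05, 4875.34), "normal"),
      row("steps", "CG", c(8627.69, 8101.77, 8589.15),
          c(3786.73, 3882.31, 4379.61), "normal"),
      # baseline sitting from the baseline-characteristics table
      row("sitting", "IG", c(526.7, 511.20, 467.76),
          c(163.7, 155.56, 168.87), "normal"),
      row("sitting", "CG", c(465.2, 464.73, 411.26),
          c(186.1, 194.56, 197.00), "normal"),
      row("walking", "IG", c(14.49, 37.05, 35.16),
          c(22.86, 92.52, 52.49), "lognormal"),
      row("walking", "CG", c(26.17, 42.37, 47.37),
          c(51.93, 86.66, 72.60), "lognormal"),
      row("moderate", "IG", c(23.30, 25.59, 32.37),
          c(28.11, 36.85, 37.68), "lognormal"),
      row("moderate", "CG", c(24.94, 15.43, 38.44),
          c(36.21, 20.08, 60.04), "lognormal"),
      row("vigorous", "IG", c(10.64, 9.13, 13.73),
          c(17.80, 15.20, 21.58), "lognormal"),
      row("vigorous", "CG", c(9.76, 6.78, 10.69),
          c(23.10, 13.48, 18.44), "lognormal")
    )
  }
}

# split n over k clusters as evenly as possible
split_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

default_clusters <- function(n_ig, n_cg) {
  # 8 worksites: 3 secondary schools, 3 commercial organizations,
  # 2 non-profits; every arm holds at least one of each type
  types <- list(
    IG = c("school", "school", "commercial", "nonprofit"),
    CG = c("school", "commercial", "commercial", "nonprofit")
  )
  rows <- lapply(c("IG", "CG"), function(arm) {
    n <- if (arm == "IG") n_ig else n_cg
    tt <- types[[arm]]
    data.frame(label = paste0(arm, "_", tt, "_", seq_along(tt)),
               type = tt, arm = arm, size = split_sizes(n, length(tt)))
  })
  do.call(rbind, rows)
}

#' Default simulation configuration from the reference trial
#'
#' Returns a `sim_config` whose parameters reproduce the published structure
#' of the reference cluster RCT: arm x wave means and SDs for daily steps,
#' sitting and the three self-reported activity domains; group sizes (65 IG /
#' 74 CG for the at-risk sample, 137 per arm for the total sample); eight
#' worksite clusters of three types; retention 101/137 (T1) and 91/137 (T2)
#' in the intervention arm versus 112/137 and 107/137 in the control arm,
#' with an elevated dropout hazard in commercial worksites.
#'
#' @param sample `"at_risk"` (participants below 10,000 steps/day at
#'   baseline) or `"total"`.
#' @return Object of class `sim_config` (a named list). Tunable fields:
#'   `n_per_arm`, `clusters`, `outcomes` (mean/SD table), `rho` (within-person
#'   test-retest correlation, default 0.6), `cluster_sd` (between-cluster SD
#'   of steps, default 0 -- the trial found no detectable worksite variance),
#'   `selfreport_bias` (multiplier on self-reported activity means, default
#'   1), `retention` (per arm, cumulative at T1/T2),
#'   `commercial_dropout_multiplier` (default 2), `truncation_cap` (20,000
#'   steps/day).
#' @examples
#' cfg <- default_sim_config("at_risk")
#' cfg$retention$IG
#' @export
default_sim_config <- function(sample = c("at_risk", "total")) {
  sample <- match.arg(sample)
  n <- if (sample == "at_risk") c(IG = 65L, CG = 74L) else c(IG = 137L, CG = 137L)
  cfg <- list(
    sample = sample,
    n_per_arm = n,
    clusters = default_clusters(n[["IG"]], n[["CG"]]),
    outcomes = outcome_defaults(sample),
    rho = 0.6,
    cluster_sd = 0,
    selfreport_bias = 1,
    retention = list(IG = c(T1 = 101 / 137, T2 = 91 / 137),
                     CG = c(T1 = 112 / 137, T2 = 107 / 137)),
    commercial_dropout_multiplier = 2,
    truncation_cap = 20000
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (any(outcomes$sd <= 0)) stopf("outcome SDs must be > 0")
    if (rho < 0 || rho >= 1) stopf("`rho` must lie in [0, 1)")
    for (arm in c("IG", "CG")) {
      r <- retention[[arm]]
      if (any(r < 0 | r > 1)) stopf("retention probabilities must lie in [0, 1]")
      if (r[["T2"]] > r[["T1"]]) stopf("retention must be non-increasing across waves")
      if (sum(clusters$size[clusters$arm == arm]) != n_per_arm[[arm]]) {
        stopf("cluster sizes must sum to n_per_arm for arm %s", arm)
      }
    }
    step_sds <- outcomes$sd[outcomes$outcome == "steps"]
    if (cluster_sd >= min(step_sds)) {
      stopf("infeasible SD decomposition: cluster_sd (%g) must be below the smallest wave SD (%g)",
            cluster_sd, min(step_sds))
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$sample, "sample:",
      paste(sprintf("%s n=%d", names(x$n_per_arm), x$n_per_arm), collapse = ", "),
      "\n  clusters:", nrow(x$clusters),
      "| rho =", x$rho, "| cluster_sd =", x$cluster_sd, "\n")
  invisible(x)
}

WAVES <- c("T0", "T1", "T2")

# per-participant substream: adding participants never perturbs earlier draws
participant_seed <- function(master, i, offset = 0L) {
  (as.numeric(master) * 100003 + i * 7 + offset) %% 2147483629
}

# elementwise moment-matched lognormal quantile; zero mean maps to zero
qlnorm_matched <- function(p, m, s) {
  out <- numeric(length(p))
  pos <- m > 0
  if (any(pos)) {
    sdlog2 <- log(1 + (s[pos] / m[pos])^2)
    out[pos] <- stats::qlnorm(p[pos], meanlog = log(m[pos]) - sdlog2 / 2,
                              sdlog = sqrt(sdlog2))
  }
  out
}

#' Simulate a fully observed cohort
#'
#' Draws a long-format participant x wave cohort under `config`. Each
#' participant carries a latent person factor shared across waves (Gaussian
#' copula with correlation `rho`), plus a worksite random intercept of SD
#' `cluster_sd` on steps. Normal outcomes (steps, sitting) are calibrated so
#' the marginal wave SDs match the config; self-report domains are drawn from
#' moment-matched lognormals (positive skew) scaled by `selfreport_bias`.
#' Steps are floored at 0 and truncated at `truncation_cap`. Each participant
#' has an independent seed substream derived from `seed`, so the cohort is
#' reproducible and extending it does not perturb existing participants.
#'
#' @param config a [default_sim_config()]-style configuration.
#' @param seed integer master seed.
#' @return Tibble with columns `participant_id`, `cluster`, `cluster_type`,
#'   `arm`, `wave`, `steps`, `sitting`, `walking`, `moderate`, `vigorous`,
#'   `observed` (all `TRUE`; see [apply_dropout()]).
#' @examples
#' cohort <- simulate_cohort(default_sim_config("at_risk"), seed = 1)
#' dplyr::count(cohort, arm, wave)
#' @export
simulate_cohort <- function(config, seed) {
  validate_sim_config(config)
  assert_scalar_number(seed, "seed")
  cl <- config$clusters
  set.seed(seed %% 2147483629)
  cluster_fx <- stats::rnorm(nrow(cl), 0, config$cluster_sd)
  names(cluster_fx) <- cl$label

  roster <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    data.frame(cluster = cl$label[i], cluster_type = cl$type[i],
               arm = cl$arm[i], n = cl$size[i])
  }))
  roster <- roster[rep(seq_len(nrow(roster)), roster$n), c("cluster", "cluster_type", "arm")]
  roster$participant_id <- sprintf("P%03d", seq_len(nrow(roster)))

  outcomes <- unique(config$outcomes$outcome)
  rho <- config$rho
  # pre-resolved parameter list: params[[arm]][[outcome]] = list(mean, sd, dist)
  params <- lapply(c(IG = "IG", CG = "CG"), function(arm) {
    lapply(stats::setNames(outcomes, outcomes), function(oc) {
      par <- config$outcomes[config$outcomes$outcome == oc &
                             config$outcomes$arm == arm, ]
      par <- par[match(WAVES, par$wave), ]
      list(mean = par$mean, sd = par$sd, dist = par$dist[1])
    })
  })
  n_p <- nrow(roster)
  vals <- array(NA_real_, dim = c(3, length(outcomes), n_p),
                dimnames = list(WAVES, outcomes, NULL))
  for (i in seq_len(n_p)) {
    set.seed(participant_seed(seed, i))
    arm_par <- params[[roster$arm[i]]]
    for (oc in outcomes) {
      u <- stats::rnorm(1)
      e <- stats::rnorm(3)
      z <- sqrt(rho) * u + sqrt(1 - rho) * e
      par <- arm_par[[oc]]
      if (par$dist == "normal") {
        if (oc == "steps") {
          sd_w <- sqrt(par$sd^2 - config$cluster_sd^2)
          x <- par$mean + cluster_fx[[roster$cluster[i]]] + sd_w * z
          x <- pmin(pmax(x, 0), config$truncation_cap)
        } else {
          x <- pmax(par$mean + par$sd * z, 0)
        }
      } else {
        x <- qlnorm_matched(stats::pnorm(z), par$mean, par$sd) *
          config$selfreport_bias
      }
      vals[, oc, i] <- x
    }
  }
  idx <- rep(seq_len(n_p), each = 3)
  out <- tibble::tibble(
    participant_id = roster$participant_id[idx],
    cluster = roster$cluster[idx],
    cluster_type = roster$cluster_type[idx],
    arm = roster$arm[idx],
    wave = rep(WAVES, n_p),
    steps = NA_real_, sitting = NA_real_, walking = NA_real_, moderate = NA_real_,
    vigorous = NA_real_, observed = TRUE
  )
  for (oc in outcomes) out[[oc]] <- as.vector(vals[, oc, ])
  out
}

#' Apply monotone differential dropout to a cohort
#'
#' Marks participants unobserved from their first missed wave onward. Dropout
#' is missing-completely-at-random within arm x cluster-type strata: each arm
#' has its cumulative retention at T1 and T2, and commercial worksites have
#' their per-wave dropout hazard multiplied by
#' `config$commercial_dropout_multiplier`. Baseline (T0) is always observed;
#' a participant observed at T2 is necessarily observed at T1 (no re-entry).
#'
#' @param cohort a fully observed cohort from [simulate_cohort()].
#' @param config the simulation configuration.
#' @param seed integer seed (independent substream per participant).
#' @return The cohort with updated `observed` flags.
#' @examples
#' cfg <- default_sim_config("at_risk")
#' cohort <- apply_dropout(simulate_cohort(cfg, 1), cfg, 1)
#' @export
apply_dropout <- function(cohort, config, seed) {
  validate_sim_config(config)
  ids <- unique(cohort$participant_id)
  info <- cohort[match(ids, cohort$participant_id),
                 c("participant_id", "arm", "cluster_type")]
  status <- lapply(seq_along(ids), function(i) {
    set.seed(participant_seed(seed, i, offset = 500000011))
    r <- config$retention[[info$arm[i]]]
    p1 <- 1 - r[["T1"]]                                  # drop before T1
    p2 <- if (r[["T1"]] > 0) 1 - r[["T2"]] / r[["T1"]] else 1  # drop T1 -> T2
    if (info$cluster_type[i] == "commercial") {
      mult <- config$commercial_dropout_multiplier
      p1 <- min(1, p1 * mult)
      p2 <- min(1, p2 * mult)
    }
    u <- stats::runif(2)
    obs1 <- u[1] >= p1
    obs2 <- obs1 && u[2] >= p2
    c(T0 = TRUE, T1 = obs1, T2 = obs2)
  })
  status <- do.call(rbind, status)
  rownames(status) <- ids
  cohort$observed <- status[cbind(cohort$participant_id, cohort$wave)]
  cohort
}

#' Simulate a trial cohort with dropout
#'
#' Convenience wrapper: [simulate_cohort()] followed by [apply_dropout()].
#'
#' @inheritParams apply_dropout
#' @param config a simulation configuration.
#' @param seed integer master seed.
#' @return A long-format cohort tibble.
#' @export
simulate_trial <- function(config = default_sim_config("total"), seed) {
  apply_dropout(simulate_cohort(config, seed), config, seed)
}
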