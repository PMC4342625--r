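---
title: "Computer-tailored step advice and cluster-trial simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computer-tailored step advice and cluster-trial simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steptailor)
```

`steptailor` packages the computational machinery of a pedometer-based,
computer-tailored physical activity intervention and of the cluster
randomized trial design used to evaluate it. This vignette is the package's
methods account: the models and rules implemented, the defaults and why they
were chosen, the numerical decisions, and what the synthetic-data tests do
and do not demonstrate.

## The advice engine

### Stage classification

The advice is toned by the participant's stage of change in the
transtheoretical model. The instrument asks two intention questions (step
more within 6 months? within 1 month?) and the pedometer week supplies the
average daily step count, so the package uses the standard staging
algorithm against the 10,000 steps/day goal:

| condition | stage |
|---|---|
| < 10,000 steps/day, no 6-month intention | precontemplation |
| < 10,000, 6-month intention only | contemplation |
| < 10,000, 1-month intention | preparation |
| ≥ 10,000 for < 6 months (or unknown duration) | action |
| ≥ 10,000 for ≥ 6 months | maintenance |

Two boundaries were genuinely open and are fixed here as package policy.
First, when both intention answers are "yes" the more proximal (1-month)
intention dominates, so the participant is staged *preparation*. Second, the
action/maintenance boundary is set at the conventional 6 months; when the
duration at goal is unknown the participant defaults to *action*, the more
actionable assumption. Below-goal participants with missing intention
answers cannot be staged and raise an error naming the missing field, since
silently defaulting would misdirect the advice tone.

### Step-goal schedule

Participants choose a weekly increment of 500 or 1000 steps. Week *k*'s
target is `baseline + k·increment`, capped at exactly 10,000, so the
schedule has `ceiling((10000 − baseline)/increment)` entries and always
terminates at the goal; a participant already at goal gets an empty schedule
and sustain-oriented feedback instead of an error, because advice is
delivered at every stage.

### Message bank

All feedback text lives in `inst/extdata/message_bank.json`, a JSON array of
`{id, determinant, pattern, stage, template}` records, so wording can be
revised without touching code. The bank is a *total function* over the legal
answer space of the questionnaire: every (determinant, answer) pair —
4 attitude items × 3 answers, 3 self-efficacy items × 3 answers, 3 support
persons × (4 support frequencies + 3 activity statuses), 7 benefits, all 45
barrier pairs, the intention patterns, pedometer familiarity — resolves to
exactly one message, with stage-specific entries taking precedence over
wildcard (`"*"`) ones. The acceptance suite enumerates this space across all
five stages and asserts zero lookup failures. Barrier feedback returns one
message per chosen barrier (exactly two); the pedometer primer appears iff
the participant is unfamiliar with pedometers. Templates carry `{steps}` and
`{goal}` placeholders rendered with `glue`; rendering is deterministic, so
identical questionnaire input yields byte-identical advice — a property the
tests assert, since reproducible tailoring is what separates rule-based
advice from ad-hoc text.

Progress feedback on repeat requests compares the previous and current
averages; the variant (improved / unchanged / declined) follows the sign of
the difference, and deltas derived from fractional means are rounded half
away from zero so a +0.5-step difference never silently becomes "unchanged".

## Pedometer data reduction

A pedometer day is valid when the count exceeds 100 (strictly) and the
device was worn at least 8 hours. Wear time is not recorded by the device;
it is reconstructed as `24 − sleep window − logged non-wear hours`, floored
at 0, with a configurable sleep window defaulting to 8 h (removal is
permitted only for sleeping and water activities, and logged water
activities are kept as annotations, not steps). Daily counts above 20,000
are truncated to 20,000 *before* averaging — truncation order matters and is
tested (a 21,000-step day inside a 6-day run contributes 20,000 to the
mean).

The wave average requires the longest run of *consecutive calendar days*
that are all valid to span at least 5 days; a single invalid day breaks the
run. The protocol's "including at least one weekend day" is implemented as a
validity flag (default on) because the instrument describes it as wearing
protocol rather than an explicit analysis rule; analysts who disagree can
turn it off. Failures return a reason code (`empty`,
`too_few_consecutive`, `no_weekend_day`) rather than `NA`, so QC summaries
can report *why* a wave was lost.

## IPAQ short-form scoring

Each domain (walking, moderate, vigorous) is converted to minutes/day as
`days/week × minutes/day ÷ 7`; total PA is their sum. Cleaning follows the
public IPAQ scoring protocol, which the source instrument cites without
restating: per-domain episodes under 10 min/day are zeroed, per-domain
minutes are capped at 180 min/day, and respondents reporting more than 960
raw activity minutes/day are flagged excluded (the flag is judged on the
raw minutes, since after capping the total can never reach 960). All three
constants are arguments with these defaults. Whether the original analysis
applied the exclusion or only the truncation is not itemized anywhere;
shipping the full protocol with an overridable flag covers both readings.

Activity outcomes are screened with a one-sample Kolmogorov–Smirnov test
against a normal with the sample's mean and SD (`exact = FALSE`, because
count-derived data are tied); when the screen rejects at α = .05 the values
are transformed to `log(x + 1)` — the `+1` admits the zeros that dominate
self-reported vigorous activity, a detail the original description leaves
open. The "positive skewness" motivation is recorded but does not make the
test one-sided: the screen is a plain normality check. A zero-variance
sample is returned untransformed rather than erroring, as a degenerate but
legal QC outcome.

## The trial simulator

The generator emulates an 8-worksite (3 schools, 3 commercial, 2
non-profit), 2-arm, 3-wave trial. Its defaults *are* the reference trial's
published conditions and are not tuned: arm × wave means and SDs for steps,
sitting and the three self-report domains; 137 participants per arm in the
total sample and 65 vs 74 in the at-risk subsample; cumulative retention
101/137 (T1) and 91/137 (T2) in the intervention arm versus 112/137 and
107/137 in control. Two structural parameters the source does not report
were fixed once: the within-person test–retest correlation ρ = 0.6 (a
typical week-to-week pedometer reliability; without it repeated-measures
power would be meaningless) and a commercial-worksite dropout hazard
multiplier of 2, reflecting the strongly differential attrition by worksite
type that the completion analysis shows without publishing rates per type.

Per participant and outcome the generator draws
`z_w = √ρ·u + √(1−ρ)·ε_w`; steps and sitting are normal
`μ_aw + σ_aw z_w` with the steps SD decomposed as
`σ²_aw = cluster_sd² + residual²` when a worksite random intercept is
requested (an infeasible decomposition is a configuration error), floored
at 0 and truncated at 20,000 — the same truncate-then-analyze order as the
data-reduction rules. Self-report domains map `Φ(z_w)` through a
moment-matched lognormal quantile, giving the configured mean and SD with
the positive skew that exercises the KS/log-transform path; a
`selfreport_bias` multiplier can inflate them to mimic over-reporting.
`cluster_sd` defaults to 0 because the trial's own three-level null model
found worksite variance indistinguishable from zero. Dropout is monotone
(no re-entry) and missing-completely-at-random within arm × worksite-type
strata, consistent with the reported absence of completer/dropout
differences. Randomness is streamed per participant from the master seed,
so enlarging a cohort never perturbs existing participants' draws.

What the generator does **not** emulate: the skewed shape of the real
baseline step distribution (marginals are Gaussian, so the simulated
"total" cohort classifies ≈ 63% of participants as at-risk rather than the
observed 69%), questionnaire psychometrics, seasonal recruitment waves, and
outcome-dependent dropout. Tests passing on this synthetic structure
therefore validate the pipeline's logic and calibration, not distributional
fidelity to any real cohort.

A deliberate bookkeeping choice: the "total" configuration takes its
baseline step means from the effect-table descriptives (the available-case
column the ANCOVAs describe) rather than the slightly lower
baseline-characteristics table, since the simulator's job is to reproduce
the effect-table structure. The source's discussion-section attrition
percentages disagree with its own flow-diagram counts; the simulator
follows the flow-diagram counts.

## The analysis pipeline

Baseline characteristics are compared with independent-sample *t* tests
(quantitative) and uncorrected Pearson chi-square tests (categorical);
characteristics significant at .05 become the default ANCOVA covariate set,
and p values in (.05, .10] are flagged borderline. On the reference
defaults this reproduces the design decision of adjusting for baseline
sitting time. The worksite-variance check is a likelihood-ratio test
between participant-intercept models with and without a worksite intercept
(ML, df = 1, statistic floored at 0 at the boundary).

The intervention test is a 2 × 2 repeated-measures ANCOVA per outcome and
wave pair. The published description names the procedure but not its
parameterization; the package tests the time × condition interaction as the
arm effect on within-participant change scores with baseline covariates,
which on balanced two-wave data is algebraically identical to the
mixed-ANOVA interaction F (asserted against an `aov` + `Error()` oracle in
the tests) and reproduces the `F(1, n − 2 − k)` degrees-of-freedom
structure of the published tables. Analyses are available-case per
outcome × contrast, matching the varying *n*s across those tables. When
the pooled outcome fails the normality screen the test runs on the
`log(x + 1)` scale while descriptive means and SDs stay on the raw scale —
reconciling raw-scale tables with a log-scale analysis statement.
Guideline attainment is `100 × (steps ≥ 10,000)/observed`, rounded half
away from zero to integer percent and reported with its raw fraction. The
completer-vs-dropout analysis defines completion as observed data at the
final wave and tests arm (2×2, df = 1), worksite type (2×3, df = 2) and the
continuous baselines (*t* tests); the 2×2 chi-square is uncorrected Pearson,
which is the convention the published dropout statistic matches to three
decimals.

## Problem sizes and calibration checks

The package's own verification runs at sizes chosen to give informative
Monte-Carlo precision: 200 replicate at-risk cohorts for the
simulator/analysis round trip (Monte-Carlo SE of the mean change ≈ 25
steps/day), 1,000 null replicates of 80-participant cohorts for the ANCOVA
type-I error (99% binomial band ≈ ±0.018 around .05), 1,000 random tables
for the chi-square closed-form equivalence at 10⁻⁹, an exhaustive schedule
check over all baselines 0–10,000 in steps of 100 for both increments, and
full enumeration of the questionnaire answer space × 5 stages for advice
totality.

## Known limitations

- The engine ships one verbatim example message per determinant plus
  neutral variants; the full production advice text (multi-paragraph,
  Dutch) was never published, so the bank is a faithful skeleton, not the
  original wording.
- Exact reproduction of the published F statistics is impossible without
  individual-level data; the pipeline reproduces the tables' *structure*
  (ns, dfs, descriptives, decision rules) and its own calibration.
- The simulator's Gaussian step marginals understate the at-risk fraction
  (above); a two-component mixture would fix this but has no published
  parameters to anchor it.
- Multilevel modeling beyond the single worksite variance-component check,
  multiple imputation, and MET-minute IPAQ scoring are out of scope.
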