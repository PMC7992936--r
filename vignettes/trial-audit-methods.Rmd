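---
title: "Auditing effect-size assumptions and ceiling effects in two-arm trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing effect-size assumptions and ceiling effects in two-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powergap)
```

## The problem

A two-arm randomized trial with a continuous primary outcome is powered
against an assumed mean difference, `MD_est`, and an assumed standard
deviation, `SD_est`. Meta-research audits of such trials repeatedly find two
weaknesses. First, `MD_est` is often optimistic: when the observed
standardized effect `d_obs = |MD| / SD_pooled` is compared with the assumed
`d_est = |MD_est| / SD_est`, the ratio `d_obs / d_est` tends to fall well
below 1, and more so at longer follow-up. Second, many primary outcomes are
bounded patient-reported outcome measures (PROMs); as cohorts recover, the
sample mean drifts toward the best attainable score and observations pile up
at the bound — a ceiling effect that compresses between-group differences
and is rarely discussed in trial reports.

powergap implements this audit as a reproducible pipeline over a flat
trial-extraction CSV, plus a synthetic registry generator with exactly the
generative structure the audit presumes, so every stage can be tested
without access to anyone's extracted data.

## Variability recovery

Trial reports rarely present variability uniformly. The pipeline recovers a
pooled SD through a fixed precedence, least-derived representation first:

1. per-arm SDs, pooled as
   `SD_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`;
2. a reported total-sample SD, accepted directly (tagged `TOTAL_SD`);
3. per-arm standard errors, inverted via `sd = se * sqrt(n)`;
4. confidence intervals, inverted via the standard identities
   (`SE = width / (2q)`), with `q` the normal quantile when the relevant
   degrees of freedom exceed 60 and the t quantile otherwise. Published
   audits typically cite the Cochrane Handbook conversions without saying
   which divisor they used; both are exposed (`ci_method = "z"` / `"t"`),
   and the df-60 switch is the default. The schema carries per-arm CIs, so
   each is inverted to an arm SD and pooled; `sd_from_ci()` additionally
   implements the difference-CI inversion for callers who have one.

Every recovery is tagged in the audit output (`sd_source`), because a value
recovered from a CI is more derived — and more assumption-laden — than a
reported SD.

## PROM-scale normalization and the ceiling screen

Each bounded scale is stored as a `(worst, best)` pair; direction is encoded
by ordering, so a pain VAS with best 0 needs no special casing. The
n-weighted mean of the two arms and the pooled SD are mapped to percent of
the best score:

- `mean_pct = 100 (mean - worst) / (best - worst)` — on a 0–50 scale with
  best 50, a weighted mean of 40 is 80%;
- `sd_pct = 100 sd / |best - worst|`.

The screen for a possible ceiling effect flags a trial when
`mean_pct + k * sd_pct > 100` with `k = 1` by default. Two conventions are
deliberate:

- the inequality is **strict** — a cohort sitting exactly 1 SD below the
  ceiling is the boundary case, and under normality the fraction of
  patients beyond the ceiling at that boundary is `1 - pnorm(1) ≈ 0.159`,
  the "roughly 16%" heuristic the flag operationalizes
  (`tail_beyond_ceiling()` reports this model-implied fraction per trial);
- `k` is configurable so a ±2 SD screen is possible, and the symmetric
  floor check (`mean_pct - k * sd_pct < 0`) is implemented but off by
  default, since in practice recovery-type outcomes crowd the ceiling.

Out-of-range native means are extraction mistakes and fail loudly rather
than being clipped; an absolute tolerance of `1e-6` of the scale range
absorbs floating-point slop only.

## Effect-size attenuation

`d_obs`, `d_est`, and their ratio are computed as absolute magnitudes —
published ratio tables do not track direction of benefit, and a signed
analysis would need an anchor the extraction schema does not carry. The
"between-group SD" in `d_obs` is the pooled SD above (not an unweighted
average of arm SDs), consistent with the pipeline's single variability
algebra. Trials missing any ingredient (no recoverable SD, no `SD_est`)
are excluded from the ratio analysis and counted, mirroring the eligibility
chains such audits report; the run manifest records every denominator.

## Report tables and conventions

Four tables reproduce the structure of a published audit: a rationale
taxonomy for `MD_est` (MCID/MDC/PASS, validation studies, prior RCTs,
observational studies, pilot data, clinical judgement, ...), a
distribution-assessment taxonomy (where `MEAN_MEDIAN_ONLY` is exclusive and
all other codes multi-count), and two cross-tabs against follow-up bins.
Printed tables of this kind mix conventions, so nothing is inferred:

- the weighted-mean × follow-up table uses **row** percents, the ratio ×
  follow-up table **column** percents (both overridable);
- follow-up bins use months = 30.4375 days and years = 365.25 days and are
  half-open on the right, so 365 days is still "6–12 months" and 730 days
  is "over 12 months"; the alternate nine-category scheme (under a day to
  over ten years) includes a 1–3-month bin so the partition is total;
- weighted-mean bins: ≤60, (60, 75], (75, 85], (85, 90), and ≥90 — the
  printed labels leave 90 ambiguous, here it belongs to the top bin; ratio
  bins are `[0, 0.5)`, `[0.5, 1)`, `[1, 1.5)`, `[1.5, ∞)` with 1.0 in the
  third bin;
- percents round to the nearest integer, halves away from zero, with one
  decimal below 1% (so 1/264 renders "0.4 %", not "0 %"); banker's
  rounding is available as `mode = "half-even"`;
- medians and IQRs use linear interpolation between order statistics
  (quantile type 7), the common default where reports state no rule.

## The synthetic registry

`generate_registry()` draws trials with the structure the audit presumes,
and nothing more specific: it matches marginals and mechanisms, not any
real study.

- **Latent recovery.** The control-arm mean sits at position
  `p(t) = b_inf - (b_inf - b0) exp(-t / tau)` of the scale range toward the
  best score (defaults `b0 = 0.55`, `b_inf = 0.92`, `tau = 120` days, ±0.05
  trial-level jitter): early follow-ups mid-scale, late follow-ups near the
  ceiling, the pattern that makes long trials ceiling-prone.
- **Censoring, not truncation.** Patient outcomes are
  `N(latent mean, sigma)` clipped to the closed scale interval, which puts
  point-mass on the bounds — the defining signature of a ceiling effect.
  `clipped_normal_moments()` gives the analytic censored-population mean
  and SD, the truth channel for recovery tests.
- **Inflated estimates.** `MD_est` is the true latent difference times a
  lognormal factor with median 2.4 (sdlog 0.5) — a tuning default chosen so
  that observed/estimated ratios land in the well-below-1 regime audits
  report, not an empirical estimate of anything.
- **Marginals.** Taxonomy multinomials proportional to published audit
  counts (41% provide any rationale; 79% report mean/median only); 56%
  PROM outcomes; 29% of trials report means without any variability;
  60% of power calculations report `SD_est`; follow-up probabilities
  (0.13, 0.23, 0.14, 0.14, 0.36) over the not-applicable/quarterly bins,
  consistent with about a third of trials past one year and two thirds at
  three months or more. Per-arm sizes are log-uniform on [20, 200] and the
  patient-level SD uniform on 15–25% of the scale range — typical of
  orthopaedic trials, not extracted from any. The true standardized effect
  is `N(0.4, 0.15)` truncated at 0.05.
- **Determinism.** One master seed spawns a per-trial sub-seed stream, so
  a registry is reproducible record-for-record regardless of how trials
  would be parallelised.

What passing tests on this generator do show: the algebra of every pipeline
stage is exact (round-trips, recovery identities, tally oracles), the
eligibility bookkeeping reconciles, and the censoring mechanism produces
the attenuation and crossover patterns the audit is designed to detect.
What they cannot show: anything about real extraction quality — skewed
outcomes, misreported CIs, non-normal score distributions, or correlated
missingness, none of which the generator emulates.

## Numerical and degenerate-input choices

- Validation is pure and never alters values; structural violations
  (missing/negative n, inverted CI, degenerate scale, negative SD or
  follow-up) reject a row with a machine-readable reason, while missing
  summaries only clear eligibility flags — a record that cannot enter one
  table can still be counted in another.
- A zero-width CI yields `sd = 0` with a warning; `sd_pct = 0` makes the
  ceiling tail 0/0.5/1 by position relative to the bound.
- An explicitly not-applicable follow-up is a first-class state (CSV
  sentinel `"NA"`), distinct from unknown (empty cell), and owns the first
  column of both cross-tabs.
- Problem sizes in the test suite — registries of 264 to 2,000 trials,
  Monte-Carlo sweeps of 500 replicates per grid point — are chosen so the
  binomial and Monte-Carlo error bars the assertions use are a few percent
  wide; they are the package's own verification sizes.

## Limitations

The audit inherits the published methodology's heuristics: the ceiling
screen is a normal-approximation statement about a censored quantity, not a
censored-model fit; magnitude-only ratios cannot distinguish a reversed
effect from an attenuated one; and SD recovery from CIs assumes the report
computed its intervals the standard way. The generator's defaults are study
conditions, fixed once — they are not fitted to any dataset, and the
pipeline's outputs on synthetic registries characterise the method, not any
body of literature.
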