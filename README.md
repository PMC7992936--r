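# powergap

Meta-research audit pipeline for two-arm randomized controlled trials with
a continuous primary outcome — for methodologists and systematic reviewers
who extract trial summaries (per-arm n / mean / SD-or-SE-or-CI, the power
calculation's assumptions, follow-up, outcome-scale bounds) and want the
audit's derived quantities and report tables computed reproducibly instead
of by spreadsheet.

## What it computes

Given one extraction record per trial, the pipeline derives:

- **Pooled variability.** `SD_pooled = sqrt(((n_a-1)s_a² + (n_b-1)s_b²) /
  (n_a+n_b-2))`, recovering arm SDs from standard errors (`sd = se·√n`) or
  confidence intervals (`SE = width / 2q`, normal or t quantile) when SDs
  are not reported, with the recovery path tagged per trial.
- **Ceiling screen.** The n-weighted mean and `SD_pooled` mapped onto the
  bounded outcome scale as percent of the best score
  (`mean_pct = 100·(mean − worst)/(best − worst)`; a mean of 40 on a 0–50
  scale is 80 %), a crossover flag when `mean_pct + k·sd_pct > 100 %`
  (default `k = 1`), and the normal-model tail beyond the ceiling
  (`1 − Φ(1) ≈ 16 %` at the flag boundary).
- **Effect-size attenuation.** `d_obs = |MD| / SD_pooled` versus the
  powered-for `d_est = |MD_est| / SD_est`, and their ratio — values below 1
  mean the trial observed less than it was powered to find.
- **Report tables.** Rationale and distribution-assessment frequency
  tables, and weighted-mean × follow-up / ratio × follow-up cross-tabs with
  the published percent conventions (row-wise and column-wise
  respectively), plus median (IQR) of the ratio per follow-up bin.

A seeded synthetic-registry generator (`generate_registry()`) draws trials
with boundary-censored normal outcomes, follow-up-dependent drift toward
the ceiling, and inflated power-calculation estimates, with a parallel
truth channel — so the whole pipeline is testable end to end.

## Worked example

```r
library(powergap)

gen   <- generate_registry(sim_config(seed = 2024))   # 264 synthetic trials
audit <- audit_registry(gen$records)                  # per-trial derivations
tabs  <- audit_report_tables(audit)

tabs$rationale_summary
#> Any rationale or reference provided
#> n = 264
#>     label count rendered
#>      NONE   143     54 %
#>  PROVIDED   121     46 %

tabs$ratio_by_followup
#> Ratio of observed to estimated effect size, by follow-up
#> percents per col ; n = 111
#>           NOT_APPLICABLE  UNDER_3M M3_TO_6M M6_TO_12M  OVER_12M
#> LT_0_5         10 (67 %) 21 (70 %) 8 (53 %) 13 (72 %) 24 (73 %)
#> R0_5_TO_1       3 (20 %)  7 (23 %) 6 (40 %)  4 (22 %)  6 (18 %)
#> R1_TO_1_5        1 (7 %)   2 (7 %)  1 (7 %)   1 (6 %)   2 (6 %)
#> GT_1_5           1 (7 %)         0        0         0   1 (3 %)

tabs$ratio_medians[6, ]
#>   followup   n median    q1    q3
#>      TOTAL 111  0.364 0.226 0.555
```

Reading this: of 264 trials, 121 (46 %) gave any rationale for their
assumed mean difference; 111 trials allowed the observed/estimated
effect-size comparison, and their median ratio of 0.36 (IQR 0.23–0.56)
says the typical trial observed roughly a third of the standardized effect
it was powered for — the under-1 regime concentrated in the `< 0.5` row at
every follow-up. In the same run, 40 of 97 scale-eligible trials tripped
the ceiling-crossover flag (`sum(audit$crossover_flag[audit$scaled_eligible])`).

File-based runs mirror this: `cmd_generate("out/")` writes
`registry.csv` + `truths.csv`, `cmd_audit("out/registry.csv", "audit/")`
writes the per-trial audit CSV, the four table CSVs, a Markdown report and
a manifest of every eligibility denominator. A thin CLI wraps both:
`Rscript inst/cli/powergap.R generate -o out/ --seed 7`.

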