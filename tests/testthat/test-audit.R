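hand_fixture <- function() {
  make_registry(
    # 0-50 scale, best 50: wm 42.5 -> 85 %, sd 10 -> 20 %, crossover
    make_record("H01", n_a = 30, mean_a = 40, sd_a = 10,
                n_b = 30, mean_b = 45, sd_b = 10,
                scale_worst = 0, scale_best = 50,
                md_est = 10, sd_est = 10, followup_days = 365),
    # reversed pain VAS: wm 2.5 -> 75 %, no crossover, ratio exactly 1
    make_record("H02", n_a = 50, mean_a = 3, sd_a = 2,
                n_b = 50, mean_b = 2, sd_b = 2,
                scale_worst = 10, scale_best = 0,
                md_est = 1, sd_est = 2, followup_days = 30),
    # SE representation; unequal arms
    make_record("H03", n_a = 10, mean_a = 0, sd_a = NA, se_a = 10 / sqrt(10),
                n_b = 30, mean_b = 100, sd_b = NA, se_b = 10 / sqrt(30),
                scale_worst = 0, scale_best = 100,
                md_est = 20, sd_est = 10, followup_days = 800),
    # no variability anywhere: countable but not scaled/ratio eligible
    make_record("H04", sd_a = NA, sd_b = NA, followup_days = 100),
    # no sd_est: scaled but not ratio eligible
    make_record("H05", n_a = 20, mean_a = 80, sd_a = 12,
                n_b = 20, mean_b = 84, sd_b = 12, sd_est = NA,
                followup_na = TRUE, followup_days = NA),
    # non-PROM, no scale: ratio eligible only
    make_record("H06", scale_worst = NA, scale_best = NA, is_prom = FALSE,
                n_a = 40, mean_a = 500, sd_a = 120,
                n_b = 40, mean_b = 560, sd_b = 120,
                md_est = 120, sd_est = 120, followup_days = 10)
  )
}

test_that("audit derives hand-computed per-trial columns", {
  audit <- audit_registry(hand_fixture())
  h <- function(id, col) audit[[col]][audit$trial_id == id]

  expect_equal(h("H01", "weighted_mean"), 42.5)
  expect_equal(h("H01", "sd_pooled"), 10)
  expect_equal(h("H01", "mean_pct"), 85)
  expect_equal(h("H01", "sd_pct"), 20)
  expect_true(h("H01", "crossover_flag"))
  expect_equal(h("H01", "tail_frac"), 1 - pnorm(0.75), tolerance = 1e-12)
  expect_equal(h("H01", "d_obs"), 0.5)
  expect_equal(h("H01", "d_est"), 1)
  expect_equal(h("H01", "ratio"), 0.5)
  expect_equal(as.character(h("H01", "mean_pct_bin")), "GT75_LE85")
  expect_equal(as.character(h("H01", "followup_bin")), "M6_TO_12M")
  expect_equal(as.character(h("H01", "ratio_bin")), "R0_5_TO_1")

  expect_equal(h("H02", "mean_pct"), 75)
  expect_equal(h("H02", "sd_pct"), 20)
  expect_false(h("H02", "crossover_flag"))
  expect_equal(h("H02", "ratio"), 1)
  expect_equal(as.character(h("H02", "ratio_bin")), "R1_TO_1_5")

  expect_equal(h("H03", "weighted_mean"), 75)
  expect_equal(h("H03", "sd_pooled"), 10, tolerance = 1e-10)
  expect_equal(h("H03", "sd_source"), "FROM_SE")
  expect_equal(h("H03", "d_obs"), 10)
  expect_equal(as.character(h("H03", "followup_bin")), "OVER_12M")

  expect_false(h("H04", "scaled_eligible"))
  expect_false(h("H04", "ratio_eligible"))
  expect_true(is.na(h("H04", "ratio")))

  expect_true(h("H05", "scaled_eligible"))
  expect_false(h("H05", "ratio_eligible"))
  expect_equal(h("H05", "mean_pct"), 82)
  expect_equal(as.character(h("H05", "followup_bin")), "NOT_APPLICABLE")

  expect_false(h("H06", "scaled_eligible"))
  expect_true(h("H06", "ratio_eligible"))
  expect_equal(h("H06", "ratio"), 0.5)
})

test_that("out-of-range extraction mistakes are excluded loudly", {
  reg <- make_registry(
    make_record("ok"),
    make_record("oor", mean_a = 120, mean_b = 130, scale_worst = 0,
                scale_best = 100)
  )
  expect_warning(audit <- audit_registry(reg), "outside the scale")
  expect_false(audit$scaled_eligible[audit$trial_id == "oor"])
  expect_true(audit$scaled_eligible[audit$trial_id == "ok"])
})

test_that("report tables use per-table denominators and axes", {
  gen <- generate_registry(sim_config(n_trials = 200, seed = 17))
  audit <- audit_registry(gen$records)
  tabs <- audit_report_tables(audit)

  expect_equal(sum(tabs$rationale$data$count), 200)
  expect_equal(tabs$rationale$denominator, 200)
  expect_equal(tabs$mean_by_followup$denominator,
               sum(audit$scaled_eligible))
  expect_equal(tabs$ratio_by_followup$denominator,
               sum(audit$ratio_eligible))
  expect_equal(tabs$mean_by_followup$percent_axis, "row")
  expect_equal(tabs$ratio_by_followup$percent_axis, "col")
  # medians table overall row agrees with a direct computation
  overall <- tabs$ratio_medians[tabs$ratio_medians$followup == "TOTAL", ]
  expect_equal(overall$median,
               median(audit$ratio[audit$ratio_eligible]))
  expect_equal(overall$n, sum(audit$ratio_eligible))
})

test_that("cmd_generate then cmd_audit chain with consistent manifests", {
  out_g <- withr::local_tempdir()
  out_a <- withr::local_tempdir()
  m_gen <- cmd_generate(out_g, config = sim_config(n_trials = 80, seed = 5))
  expect_true(file.exists(file.path(out_g, "registry.csv")))
  expect_true(file.exists(file.path(out_g, "truths.csv")))
  expect_true(file.exists(file.path(out_g, "manifest.json")))
  expect_equal(m_gen$counts$records, 80)

  res <- cmd_audit(file.path(out_g, "registry.csv"), out_a)
  for (f in res$manifest$outputs) {
    expect_true(file.exists(file.path(out_a, f)), info = f)
  }
  cnt <- res$manifest$counts
  # eligibility chain is non-increasing
  chain <- c(cnt$records, cnt$power_calc, cnt$outcome_summaries, cnt$scaled)
  expect_true(all(diff(chain) <= 0))
  expect_lte(cnt$ratio_eligible, cnt$outcome_summaries)
  # manifest JSON parses and echoes the chain
  js <- jsonlite::read_json(file.path(out_a, "manifest.json"))
  expect_equal(js$counts$records, 80)
  expect_equal(js$tool, "powergap")

  # determinism: same seed regenerates byte-identical registries
  out_g2 <- withr::local_tempdir()
  cmd_generate(out_g2, config = sim_config(n_trials = 80, seed = 5))
  expect_identical(readLines(file.path(out_g, "registry.csv")),
                   readLines(file.path(out_g2, "registry.csv")))

  # idempotence: rerunning the audit reproduces byte-identical tables
  out_a2 <- withr::local_tempdir()
  cmd_audit(file.path(out_g, "registry.csv"), out_a2)
  for (f in c("audit.csv", "table_rationale.csv", "table_distribution.csv",
              "table_mean_by_followup.csv", "table_ratio_by_followup.csv",
              "table_ratio_medians.csv", "report.md")) {
    expect_identical(readLines(file.path(out_a, f)),
                     readLines(file.path(out_a2, f)), info = f)
  }
})

test_that("registries with no PROM trials still audit, with a warning", {
  reg <- make_registry(lapply(1:6, function(i) {
    make_record(paste0("NP", i), scale_worst = NA, scale_best = NA,
                is_prom = FALSE)
  }))
  out <- withr::local_tempdir()
  expect_warning(res <- cmd_audit(reg, out), "no scale-eligible")
  expect_equal(sum(res$tables$mean_by_followup$counts), 0)
  expect_gt(sum(res$tables$ratio_by_followup$counts), 0)
})

test_that("run configuration loads from YAML and drives generation", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 77", "sim:", "  n_trials: 15"), cfg_path)
  out <- withr::local_tempdir()
  m <- cmd_generate(out, config = cfg_path)
  expect_equal(m$counts$records, 15)
  expect_equal(m$seed, 77)
  expect_error(load_run_config("does-not-exist.yaml"), "not found")
})
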