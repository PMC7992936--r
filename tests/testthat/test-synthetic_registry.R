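test_that("latent mean recovery has the right endpoints and closed form", {
  expect_equal(latent_mean_at(0, 0, 100, b0 = 0.5, b_inf = 0.9,
                              tau_days = 120), 50)
  expect_equal(latent_mean_at(1e9, 0, 100, b0 = 0.5, b_inf = 0.9,
                              tau_days = 120), 90, tolerance = 1e-6)
  # t = tau: b_inf - (b_inf - b0) / e
  expect_equal(latent_mean_at(120, 0, 100, b0 = 0.5, b_inf = 0.9,
                              tau_days = 120),
               100 * (0.9 - 0.4 * exp(-1)), tolerance = 1e-9)
  # monotone toward the ceiling, in both scale directions
  t_grid <- seq(0, 2000, by = 50)
  up <- latent_mean_at(t_grid, 0, 100)
  down <- latent_mean_at(t_grid, 10, 0)
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) < 0))  # toward best = 0
  expect_error(latent_mean_at(10, 0, 100, tau_days = 0), "tau")
  # not-applicable follow-up sits at the baseline position
  expect_equal(latent_mean_at(NA, 0, 100, b0 = 0.5), 50)
})

test_that("clipped-normal moments match Monte Carlo", {
  set.seed(61)
  cases <- list(c(mu = 80, sigma = 20, lo = 0, hi = 100),
                c(mu = 100, sigma = 15, lo = 0, hi = 100),
                c(mu = 30, sigma = 5, lo = 0, hi = 100))
  for (cs in cases) {
    x <- pmin(pmax(rnorm(2e5, cs["mu"], cs["sigma"]), cs["lo"]), cs["hi"])
    mom <- clipped_normal_moments(cs[["mu"]], cs[["sigma"]], cs[["lo"]],
                                  cs[["hi"]])
    expect_equal(mom$mean, mean(x), tolerance = 0.01)
    expect_equal(mom$sd, sd(x), tolerance = 0.01)
    expect_equal(mom$p_hi, mean(x == cs[["hi"]]), tolerance = 0.02)
  }
  # infinite bounds recover the latent normal
  mom <- clipped_normal_moments(5, 2, -Inf, Inf)
  expect_equal(mom$mean, 5)
  expect_equal(mom$sd, 2)
})

test_that("simulate_arm censors at the bounds, not truncates", {
  set.seed(3)
  # mean at the best score: about half the draws clip onto the ceiling
  arm <- simulate_arm(100, 15, 2e4, worst = 0, best = 100)
  expect_equal(arm$ceiling_fraction, 0.5, tolerance = 0.02)
  expect_lte(arm$mean, 100)
  # mid-scale, sd = range/10: clipping negligible, mean unbiased
  arm2 <- simulate_arm(50, 10, 1e4, worst = 0, best = 100)
  expect_equal(arm2$ceiling_fraction, 0)
  expect_equal(arm2$mean, 50, tolerance = 3 * 10 / sqrt(1e4))
  # reversed direction: ceiling is the low end
  arm3 <- simulate_arm(0, 2, 2e4, worst = 10, best = 0)
  expect_equal(arm3$ceiling_fraction, 0.5, tolerance = 0.02)
  # unbounded arm never clips
  arm4 <- simulate_arm(50, 10, 5000)
  expect_equal(arm4$ceiling_fraction, 0)
})

test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_trials = 40, seed = 123)
  g1 <- generate_registry(cfg)
  g2 <- generate_registry(cfg)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truths, g2$truths)
  g3 <- generate_registry(sim_config(n_trials = 40, seed = 124))
  expect_false(identical(g1$records$mean_a, g3$records$mean_a))
  # byte-identical files on rerun
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_registry(g1$records, p1)
  write_registry(g2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generated registries are valid and structurally faithful", {
  cfg <- sim_config(n_trials = 264, seed = 2021)
  gen <- generate_registry(cfg)
  expect_equal(nrow(gen$records), 264)
  expect_equal(nrow(validate_records(gen$records)$rejections), 0)
  rec <- gen$records
  # missing-variability fraction near its setting (binomial tolerance)
  p_miss <- cfg$p_missing_variability
  expect_lt(abs(mean(gen$truths$variability_kind == "none") - p_miss),
            3 * sqrt(p_miss * (1 - p_miss) / 264))
  # PROM trials carry scales, non-PROM do not
  expect_true(all(!is.na(rec$scale_best[rec$is_prom])))
  expect_true(all(is.na(rec$scale_best[!rec$is_prom])))
  # md_est inflated relative to the true latent difference
  expect_equal(rec$md_est, gen$truths$delta * gen$truths$inflation,
               tolerance = 1e-12)
  expect_true(all(rec$md_est > 0))
})

test_that("taxonomy marginals track their multinomials at n = 264", {
  cfg <- sim_config(n_trials = 264, seed = 7)
  gen <- generate_registry(cfg)
  w <- cfg$rationale_weights / sum(cfg$rationale_weights)
  counts <- table(factor(gen$records$rationale,
                         levels = names(cfg$rationale_weights)))
  for (code in names(w)) {
    p <- w[[code]]
    se3 <- 3 * sqrt(264 * p * (1 - p))
    expect_lte(abs(counts[[code]] - 264 * p), max(se3, 1),
               label = paste("rationale", code))
  }
  only <- grepl("MEAN_MEDIAN_ONLY", gen$records$distribution_codes)
  p <- cfg$p_mean_median_only
  expect_lte(abs(sum(only) - 264 * p), 3 * sqrt(264 * p * (1 - p)))
  # exclusivity invariant of the code sets
  expect_true(all(gen$records$distribution_codes[only] ==
                    "MEAN_MEDIAN_ONLY"))
})

test_that("pipeline crossover fraction recovers the truth-channel fraction", {
  gen <- generate_registry(sim_config(n_trials = 2000, seed = 31415))
  audit <- audit_registry(gen$records)
  est <- mean(audit$crossover_flag[audit$scaled_eligible])
  truth_all <- gen$truths$pop_crossover[gen$truths$is_prom]
  truth <- mean(truth_all, na.rm = TRUE)
  # estimate from ~1400 sampled trials vs the analytic censored-population
  # flag; binomial error plus boundary-flip noise
  # scale-eligible is roughly p_prom * (1 - p_missing) of 2,000
  n_eff <- sum(audit$scaled_eligible)
  expect_gt(n_eff, 600)
  expect_lt(abs(est - truth), 3 * sqrt(truth * (1 - truth) / n_eff) + 0.03)
})

test_that("observed effect size attenuates toward the ceiling", {
  att <- attenuation_summary(positions = c(0.5, 0.6, 0.7, 0.85, 0.95),
                             d_true = 0.4, n_per_arm = 60, R = 500,
                             seed = 99)
  # strict one-sided comparison at the extremes
  expect_lt(att$mean_d_obs[5], att$mean_d_obs[1])
  # non-increasing across the grid up to Monte-Carlo jitter
  mc_se <- 0.4 / sqrt(500)  # generous bound on the per-point SE
  expect_true(all(diff(att$mean_d_obs) < 3 * mc_se))
  # censoring removed: d_obs unbiased for the true standardized effect
  att_free <- attenuation_summary(positions = c(0.5, 0.95), d_true = 0.4,
                                  n_per_arm = 60, R = 500, seed = 99,
                                  worst = NULL, best = NULL)
  expect_equal(att_free$mean_d_obs, rep(0.4, 2), tolerance = 0.05)
  expect_error(attenuation_summary(R = 1), "R")
})

test_that("degenerate and null generator settings behave as expected", {
  # no-attenuation null: inflation pinned at 1, means mid-scale, small sd
  cfg <- sim_config(n_trials = 120, seed = 55,
                    inflation_meanlog = 0, inflation_sdlog = 0,
                    b0 = 0.5, b_inf = 0.5, sigma_frac_range = c(0.05, 0.08),
                    p_missing_variability = 0, p_sd_est = 1)
  gen <- generate_registry(cfg)
  audit <- audit_registry(gen$records)
  ratios <- audit$ratio[audit$ratio_eligible]
  # observed standardized effect centred on the (uninflated) estimate
  expect_equal(median(ratios), 1, tolerance = 0.15)
  # empty registry contract
  g0 <- generate_registry(sim_config(n_trials = 0))
  expect_equal(nrow(g0$records), 0)
  expect_error(sim_config(n_trials = 10, bogus = 1), "unknown")
  expect_error(sim_config(tau_days = -1), "tau_days")
})
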