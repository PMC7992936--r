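# Builders for hand-made trial records used across the suite.

make_record <- function(trial_id = "T1",
                        n_a = 30, mean_a = 50, sd_a = 10,
                        se_a = NA, ci_low_a = NA, ci_high_a = NA,
                        ci_level_a = NA,
                        n_b = 30, mean_b = 45, sd_b = 10,
                        se_b = NA, ci_low_b = NA, ci_high_b = NA,
                        ci_level_b = NA,
                        sd_total = NA,
                        scale_worst = 0, scale_best = 100, is_prom = TRUE,
                        md_est = 10, sd_est = 20, rationale = "NONE",
                        followup_days = 365, followup_na = FALSE,
                        distribution_codes = "MEAN_MEDIAN_ONLY",
                        ceiling_discussed = FALSE) {
  tibble::tibble(
    trial_id = trial_id,
    n_a = as.numeric(n_a), mean_a = as.numeric(mean_a),
    sd_a = as.numeric(sd_a), se_a = as.numeric(se_a),
    ci_low_a = as.numeric(ci_low_a), ci_high_a = as.numeric(ci_high_a),
    ci_level_a = as.numeric(ci_level_a),
    n_b = as.numeric(n_b), mean_b = as.numeric(mean_b),
    sd_b = as.numeric(sd_b), se_b = as.numeric(se_b),
    ci_low_b = as.numeric(ci_low_b), ci_high_b = as.numeric(ci_high_b),
    ci_level_b = as.numeric(ci_level_b),
    sd_total = as.numeric(sd_total),
    scale_worst = as.numeric(scale_worst),
    scale_best = as.numeric(scale_best),
    is_prom = is_prom,
    md_est = as.numeric(md_est), sd_est = as.numeric(sd_est),
    rationale = rationale,
    followup_days = as.numeric(followup_days), followup_na = followup_na,
    distribution_codes = distribution_codes,
    ceiling_discussed = ceiling_discussed
  )
}

make_registry <- function(...) {
  dplyr::bind_rows(...)
}

# independent two-sample pooled SD straight from raw observations
raw_pooled_sd <- function(x_a, x_b) {
  n_a <- length(x_a)
  n_b <- length(x_b)
  sqrt((sum((x_a - mean(x_a))^2) + sum((x_b - mean(x_b))^2)) /
         (n_a + n_b - 2))
}
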