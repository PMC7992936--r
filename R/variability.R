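# Variability algebra: SD recovery from SE/CI, pooling, weighted means.
# Conversions follow the Cochrane Handbook identities for two-arm summaries.

#' Recover an SD from a standard error of the mean
#'
#' `sd = se * sqrt(n)` — the inverse of the definition of the standard
#' error of a single arm's mean.
#'
#' @param se Standard error, >= 0.
#' @param n Arm sample size, >= 1.
#' @return Standard deviation in native units.
#' @export
#' @examples
#' sd_from_se(1, 100)   # 10
#' sd_from_se(2.5, 16)  # 10
sd_from_se <- function(se, n) {
  stopifnot(all(n >= 1), all(se >= 0))
  se * sqrt(n)
}

#' Recover a pooled SD from a confidence interval of the mean difference
#'
#' Inverts the standard CI of a two-sample mean difference:
#' `SE_diff = (upper - lower) / (2 * q)` with `q` the normal (large-sample)
#' or t quantile at `(1 + level) / 2`, then
#' `sd = SE_diff / sqrt(1/n_a + 1/n_b)`.
#'
#' With `method = "auto"` (default) the z quantile is used when
#' `n_a + n_b - 2 > 60` and the t quantile with `df = n_a + n_b - 2`
#' otherwise; `"z"` and `"t"` force one divisor.
#'
#' @param lower,upper CI endpoints, `lower <= upper`.
#' @param n_a,n_b Arm sample sizes.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param method `"auto"`, `"z"`, or `"t"`.
#' @return Pooled standard deviation in native units. A zero-width CI
#'   returns 0 with a warning.
#' @export
#' @examples
#' sd_from_ci(0, 3.92, 200, 200)  # SE_diff = 1, sd = 10
sd_from_ci <- function(lower, upper, n_a, n_b, level = 0.95,
                       method = c("auto", "z", "t")) {
  method <- match.arg(method)
  stopifnot(all(lower <= upper), all(level > 0 & level < 1),
            all(n_a >= 1), all(n_b >= 1))
  df <- n_a + n_b - 2
  p <- (1 + level) / 2
  q <- switch(method,
    z = qnorm(p),
    t = qt(p, df),
    auto = ifelse(df > 60, qnorm(p), qt(p, pmax(df, 1)))
  )
  if (any(upper == lower)) {
    warning("zero-width confidence interval; returning sd = 0")
  }
  se_diff <- (upper - lower) / (2 * q)
  se_diff / sqrt(1 / n_a + 1 / n_b)
}

#' Pooled two-arm standard deviation
#'
#' `sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))` — the
#' usual equal-variance pooling of two arm SDs; always lies between the
#' two arm SDs.
#'
#' @param n_a,n_b Arm sample sizes, with `n_a + n_b >= 3`.
#' @param s_a,s_b Arm standard deviations, >= 0.
#' @return Pooled SD in native units.
#' @export
#' @examples
#' pooled_sd(20, 8, 20, 12)  # sqrt(104) = 10.198...
pooled_sd <- function(n_a, s_a, n_b, s_b) {
  stopifnot(all(n_a + n_b >= 3), all(s_a >= 0), all(s_b >= 0))
  sqrt(((n_a - 1) * s_a^2 + (n_b - 1) * s_b^2) / (n_a + n_b - 2))
}

#' Sample-size-weighted mean of two arm means
#'
#' @param n_a,n_b Arm sample sizes, >= 1.
#' @param mean_a,mean_b Arm means, native units.
#' @return `(n_a * mean_a + n_b * mean_b) / (n_a + n_b)`.
#' @export
weighted_mean <- function(n_a, mean_a, n_b, mean_b) {
  stopifnot(all(n_a >= 1), all(n_b >= 1))
  (n_a * mean_a + n_b * mean_b) / (n_a + n_b)
}

#' Pooled outcome summary of a trial record
#'
#' Applies the recovery precedence per-arm SDs > total-sample SD > per-arm
#' SEs > difference CI (least-derived representation first) to obtain the
#' trial's pooled SD, together with the n-weighted mean. The `source`
#' column records the recovery path for audit: `BOTH_SD`, `TOTAL_SD`,
#' `FROM_SE`, `FROM_CI`, or `NONE` when no representation is recoverable.
#'
#' When the variability comes through per-arm CIs of each arm mean they are
#' first inverted to per-arm SDs (`sd = sqrt(n) * width / (2q)`) and pooled;
#' a CI attached to only one arm with matching bounds on the other is not
#' guessed at.
#'
#' @param records Validated registry tibble.
#' @param ci_method Divisor rule passed to CI inversions (see
#'   [sd_from_ci()]).
#' @return Tibble with `trial_id`, `n_total`, `weighted_mean`, `sd_pooled`,
#'   `source`, row-aligned with `records`.
#' @export
pooled_summary <- function(records, ci_method = c("auto", "z", "t")) {
  ci_method <- match.arg(ci_method)
  n <- nrow(records)
  wm <- ifelse(!is.na(records$mean_a) & !is.na(records$mean_b),
               weighted_mean(records$n_a, records$mean_a,
                             records$n_b, records$mean_b),
               NA_real_)

  arm_sd <- function(arm) {
    sd_col <- records[[paste0("sd_", arm)]]
    se_col <- records[[paste0("se_", arm)]]
    nn <- records[[paste0("n_", arm)]]
    lo <- records[[paste0("ci_low_", arm)]]
    hi <- records[[paste0("ci_high_", arm)]]
    lv <- records[[paste0("ci_level_", arm)]]
    lv <- ifelse(is.na(lv), 0.95, lv)
    p <- (1 + lv) / 2
    df1 <- pmax(nn - 1, 1)
    q <- switch(ci_method,
      z = qnorm(p),
      t = qt(p, df1),
      auto = ifelse(df1 > 60, qnorm(p), qt(p, df1)))
    from_ci <- sqrt(nn) * (hi - lo) / (2 * q)
    src <- ifelse(!is.na(sd_col), "SD",
           ifelse(!is.na(se_col), "SE",
           ifelse(!is.na(lo) & !is.na(hi), "CI", "NONE")))
    value <- ifelse(src == "SD", sd_col,
             ifelse(src == "SE", se_col * sqrt(nn),
             ifelse(src == "CI", from_ci, NA_real_)))
    list(value = value, src = src)
  }
  a <- arm_sd("a")
  b <- arm_sd("b")

  sp <- rep(NA_real_, n)
  source <- rep("NONE", n)

  both_sd <- a$src == "SD" & b$src == "SD"
  tot <- !both_sd & !is.na(records$sd_total)
  both_se <- !both_sd & !tot & a$src %in% c("SD", "SE") &
    b$src %in% c("SD", "SE")
  both_ci <- !both_sd & !tot & !both_se & a$src != "NONE" & b$src != "NONE"

  pool_ok <- (both_sd | both_se | both_ci) & (records$n_a + records$n_b >= 3)
  sp[pool_ok] <- pooled_sd(records$n_a[pool_ok], a$value[pool_ok],
                           records$n_b[pool_ok], b$value[pool_ok])
  sp[tot] <- records$sd_total[tot]
  source[both_sd & pool_ok] <- "BOTH_SD"
  source[tot] <- "TOTAL_SD"
  source[both_se & pool_ok] <- "FROM_SE"
  source[both_ci & pool_ok] <- "FROM_CI"

  tibble::tibble(
    trial_id = records$trial_id,
    n_total = records$n_a + records$n_b,
    weighted_mean = wm,
    sd_pooled = sp,
    source = source
  )
}
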