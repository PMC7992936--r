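# Observed and estimated standardized effect sizes and their ratio — the
# attenuation statistic comparing what a trial found against what it was
# powered to find.

#' Observed standardized effect size
#'
#' `|mean_a - mean_b| / sd_pooled`: the absolute observed mean difference
#' in pooled-SD units (a magnitude-only Cohen's d from summary data).
#' Direction of benefit is not tracked.
#'
#' @param mean_a,mean_b Arm means, native units.
#' @param sd_pooled Pooled SD, > 0.
#' @return Non-negative standardized effect size.
#' @export
#' @examples
#' observed_effect_size(50, 45, 10)  # 0.5
observed_effect_size <- function(mean_a, mean_b, sd_pooled) {
  if (any(sd_pooled <= 0 & abs(mean_a - mean_b) > 0, na.rm = TRUE)) {
    stop("sd_pooled must be > 0 when the mean difference is nonzero")
  }
  ifelse(sd_pooled == 0 & mean_a == mean_b, 0,
         abs(mean_a - mean_b) / sd_pooled)
}

#' Estimated standardized effect size from a power calculation
#'
#' `|md_est| / sd_est`: the effect size a trial's sample-size calculation
#' assumed. Trials whose power calculation reports no SD estimate have no
#' estimated effect size and drop out of the ratio analysis (returned as
#' `NA`, not an error — in published audits well under half of trials
#' permit the comparison).
#'
#' @param md_est Assumed mean difference, native units.
#' @param sd_est Assumed SD, > 0 where present; `NA` allowed.
#' @return Standardized effect size, `NA` where `sd_est` is missing.
#' @export
estimated_effect_size <- function(md_est, sd_est) {
  stopifnot(all(sd_est > 0, na.rm = TRUE))
  ifelse(is.na(md_est) | is.na(sd_est), NA_real_, abs(md_est) / sd_est)
}

#' Ratio of observed to estimated effect size
#'
#' `d_obs / d_est`. Values below 1 mean the trial observed a smaller
#' standardized effect than it was powered for; both inputs are taken as
#' absolute magnitudes upstream, so the ratio is non-negative.
#'
#' @param d_obs Observed standardized effect size, >= 0.
#' @param d_est Estimated standardized effect size, > 0.
#' @return Non-negative ratio.
#' @export
#' @examples
#' effect_size_ratio(0.25, 0.5)  # 0.5
effect_size_ratio <- function(d_obs, d_est) {
  if (any(d_est <= 0, na.rm = TRUE)) stop("d_est must be > 0")
  d_obs / d_est
}
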