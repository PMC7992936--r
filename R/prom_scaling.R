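# Normalization of outcome summaries onto a bounded PROM scale as
# percent-of-best-score, ceiling crossover flags, and the normal-tail
# fraction implied beyond the ceiling.

.scale_check <- function(worst, best) {
  stopifnot(all(!is.na(worst)), all(!is.na(best)))
  if (any(worst == best)) stop("DEGENERATE_SCALE: best_score equals worst_score")
}

#' Convert a native-scale mean to percent of the best score
#'
#' `100 * (mean - worst) / (best - worst)`, so 0% is the worst attainable
#' score and 100% the best (the ceiling), whichever end of the instrument
#' that is: a 0-50 scale with best 50 maps a mean of 40 to 80%, and a pain
#' VAS with worst 10 / best 0 maps a mean of 3 to 70%. The conversion is
#' invariant under affine rescaling of the instrument and under reflecting
#' its direction.
#'
#' A mean outside the scale range is an extraction mistake and errors
#' (`OUT_OF_RANGE`) rather than being clipped; `tol` (absolute, default
#' 1e-6 of the range) absorbs floating-point slop at the endpoints.
#'
#' @param mean Native-scale mean (vectorised).
#' @param worst,best Scale endpoints, `worst != best`.
#' @param tol Absolute tolerance for out-of-range checks.
#' @return Percent of best score in `[0, 100]`.
#' @export
#' @examples
#' to_scale_percent(40, 0, 50)  # 80
#' to_scale_percent(3, 10, 0)   # 70
to_scale_percent <- function(mean, worst, best,
                             tol = 1e-6 * abs(best - worst)) {
  .scale_check(worst, best)
  lo <- pmin(worst, best)
  hi <- pmax(worst, best)
  out_of_range <- !is.na(mean) & (mean < lo - tol | mean > hi + tol)
  if (any(out_of_range)) {
    stop("OUT_OF_RANGE: mean outside scale bounds [",
         paste(range(lo, hi), collapse = ", "), "]: ",
         paste(utils::head(mean[out_of_range], 3), collapse = ", "))
  }
  pct <- 100 * (mean - worst) / (best - worst)
  pmin(pmax(pct, 0), 100)  # snap float slop at the endpoints only
}

#' Convert a native-scale SD to percent of the scale range
#'
#' `100 * sd / |best - worst|`; direction-free.
#'
#' @param sd Native-scale SD, >= 0.
#' @param worst,best Scale endpoints.
#' @return SD in percent units.
#' @export
#' @examples
#' sd_to_percent(10, 0, 50)  # 20
sd_to_percent <- function(sd, worst, best) {
  .scale_check(worst, best)
  stopifnot(all(sd >= 0, na.rm = TRUE))
  100 * sd / abs(best - worst)
}

#' Ceiling (or floor) crossover flag
#'
#' A trial is flagged when the weighted mean plus `k` pooled SDs, both in
#' percent of the best score, strictly exceeds 100% — the sample sat close
#' enough to the ceiling that a nominal mean +/- k SD interval leaves the
#' instrument's range, the audit's screening signal for a possible ceiling
#' effect. Exactly reaching 100 is not flagged. `floor_crossover()` is the
#' symmetric check against 0% (mean minus k SDs strictly below 0).
#'
#' @param mean_pct Weighted mean, percent of best score.
#' @param sd_pct Pooled SD, percent units.
#' @param k Multiplier on the SD; default 1.
#' @return Logical flag, vectorised.
#' @export
#' @examples
#' ceiling_crossover(85, 20)  # TRUE:  85 + 20 = 105 > 100
#' ceiling_crossover(80, 20)  # FALSE: exactly 100
ceiling_crossover <- function(mean_pct, sd_pct, k = 1) {
  mean_pct + k * sd_pct > 100
}

#' @rdname ceiling_crossover
#' @export
floor_crossover <- function(mean_pct, sd_pct, k = 1) {
  mean_pct - k * sd_pct < 0
}

#' Model-implied fraction of patients beyond the ceiling
#'
#' Upper-tail probability above 100% of a normal distribution with the
#' trial's mean and SD in percent units: the fraction of patients the
#' normal model would place at or beyond the best score were the latent
#' outcome unbounded. When the mean sits exactly 1 SD below the ceiling
#' this is `1 - pnorm(1)`, approximately 16% — the familiar one-sided
#' normal tail.
#'
#' @param mean_pct Mean, percent of best score.
#' @param sd_pct SD, percent units, >= 0. At `sd_pct = 0` the convention is
#'   0 below the ceiling, 1 above it, and 0.5 exactly at it.
#' @return Tail probability in `[0, 1]`.
#' @export
#' @examples
#' tail_beyond_ceiling(84, 16)  # 0.1587
#' tail_beyond_ceiling(60, 20)  # 1 - pnorm(2)
tail_beyond_ceiling <- function(mean_pct, sd_pct) {
  stopifnot(all(sd_pct >= 0, na.rm = TRUE))
  out <- pnorm(100, mean = mean_pct, sd = sd_pct, lower.tail = FALSE)
  degenerate <- !is.na(sd_pct) & sd_pct == 0
  if (any(degenerate)) {
    out[degenerate] <- ifelse(mean_pct[degenerate] < 100, 0,
                              ifelse(mean_pct[degenerate] > 100, 1, 0.5))
  }
  out
}
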