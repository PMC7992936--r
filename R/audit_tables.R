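# Categorization schemes and report tables: follow-up / mean-percent /
# ratio bins, percent rendering, frequency tables and cross-tabulations.

DAYS_PER_MONTH <- 30.4375   # 365.25 / 12
DAYS_PER_YEAR <- 365.25

#' Follow-up bin levels
#'
#' @param scheme `"quarters"` — the cross-tab scheme (not applicable,
#'   under 3 months, 3-6, 6-12, over 12 months) — or `"nine"`, the finer
#'   nine-category view from under a day to over ten years.
#' @return Character vector of bin codes in order.
#' @export
followup_levels <- function(scheme = c("quarters", "nine")) {
  scheme <- match.arg(scheme)
  if (scheme == "quarters") {
    c("NOT_APPLICABLE", "UNDER_3M", "M3_TO_6M", "M6_TO_12M", "OVER_12M")
  } else {
    c("NOT_APPLICABLE", "UNDER_1D", "D1_TO_1W", "W1_TO_1M", "M1_TO_3M",
      "M3_TO_1Y", "Y1_TO_3Y", "Y3_TO_10Y", "OVER_10Y")
  }
}

#' Bin a follow-up time
#'
#' Deterministic binning of follow-up in days, with months = 30.4375 days
#' and years = 365.25 days. All time bins are half-open on the right
#' (`[a, b)`), so 365 days falls within 12 months (365 < 365.25) while 730
#' days is over 12 months. The nine-category scheme runs under-a-day,
#' 1 day-1 week, 1 week-1 month, 1-3 months, 3 months-1 year, 1-3 years,
#' 3-10 years, over 10 years (the 1-3-month bin completes the partition).
#'
#' @param days Follow-up in days, >= 0; `NA` allowed when `na_flag` set.
#' @param na_flag Logical: follow-up explicitly not applicable (length-of-
#'   stay-style outcomes).
#' @param scheme See [followup_levels()].
#' @return Factor over the scheme's levels; unknown follow-up is `NA`.
#' @export
#' @examples
#' bin_followup(c(365, 730), scheme = "quarters")
bin_followup <- function(days, na_flag = rep(FALSE, length(days)),
                         scheme = c("quarters", "nine")) {
  scheme <- match.arg(scheme)
  if (any(days < 0, na.rm = TRUE)) stop("negative follow-up")
  lv <- followup_levels(scheme)
  breaks <- if (scheme == "quarters") {
    c(0, 3, 6, 12) * DAYS_PER_MONTH
  } else {
    c(0, 1, 7, DAYS_PER_MONTH, 3 * DAYS_PER_MONTH, DAYS_PER_YEAR,
      3 * DAYS_PER_YEAR, 10 * DAYS_PER_YEAR)
  }
  idx <- findInterval(days, breaks, left.open = FALSE) # [a, b) bins
  out <- lv[-1][idx]
  out[na_flag %in% TRUE] <- "NOT_APPLICABLE"
  factor(out, levels = lv)
}

#' Weighted-mean percent bin levels
#' @return Codes in order: `<=60`, `(60,75]`, `(75,85]`, `(85,90)`, `>=90`.
#' @export
mean_pct_levels <- function() {
  c("LE_60", "GT60_LE75", "GT75_LE85", "GT85_LT90", "GE_90")
}

#' Bin a weighted mean expressed as percent of the best score
#'
#' Bins follow the published row scheme: at or under 60%; over 60 and at
#' most 75; over 75 and at most 85; over 85 and under 90; 90% and above
#' (the labels leave 90 ambiguous — here exactly 90 goes to the top bin).
#'
#' @param mean_pct Percent of best score, in `[0, 100]`.
#' @return Factor over [mean_pct_levels()].
#' @export
#' @examples
#' bin_mean_pct(c(60, 85, 87.3, 90))
bin_mean_pct <- function(mean_pct) {
  if (any(mean_pct < 0 | mean_pct > 100, na.rm = TRUE)) {
    stop("mean_pct outside [0, 100]")
  }
  lv <- mean_pct_levels()
  out <- ifelse(is.na(mean_pct), NA_character_,
         ifelse(mean_pct <= 60, "LE_60",
         ifelse(mean_pct <= 75, "GT60_LE75",
         ifelse(mean_pct <= 85, "GT75_LE85",
         ifelse(mean_pct < 90, "GT85_LT90", "GE_90")))))
  factor(out, levels = lv)
}

#' Effect-size-ratio bin levels
#' @return Codes in order for `[0, 0.5)`, `[0.5, 1)`, `[1, 1.5)`, `[1.5, Inf)`.
#' @export
ratio_levels <- function() {
  c("LT_0_5", "R0_5_TO_1", "R1_TO_1_5", "GT_1_5")
}

#' Bin an observed/estimated effect-size ratio
#'
#' Half-open bins `[0, 0.5)`, `[0.5, 1.0)`, `[1.0, 1.5)`, `[1.5, Inf)`;
#' a ratio of exactly 1 lands in the 1.0-1.5 bin.
#'
#' @param ratio Non-negative ratio.
#' @return Factor over [ratio_levels()].
#' @export
bin_ratio <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE)) stop("negative ratio")
  lv <- ratio_levels()
  idx <- findInterval(ratio, c(0, 0.5, 1, 1.5))
  factor(lv[idx], levels = lv)
}

.round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Render a count as a percent string
#'
#' Nearest-integer percent, rounding halves away from zero by default
#' (`"half-even"` uses banker's rounding); nonzero percents below 1 are
#' shown with one decimal so rare categories do not render as "0 %".
#'
#' @param count Non-negative count.
#' @param denominator Positive denominator.
#' @param mode `"half-away"` (default) or `"half-even"`.
#' @return Display string such as `"41 %"` or `"0.4 %"`.
#' @export
#' @examples
#' render_percent(108, 264)  # "41 %"
#' render_percent(1, 264)    # "0.4 %"
render_percent <- function(count, denominator,
                           mode = c("half-away", "half-even")) {
  mode <- match.arg(mode)
  if (any(denominator <= 0)) stop("denominator must be > 0")
  pct <- 100 * count / denominator
  rnd <- function(x, d) {
    if (mode == "half-away") .round_half_away(x, d) else round(x, d)
  }
  out <- character(length(pct))
  small <- pct > 0 & pct < 1
  out[!small] <- paste0(format(rnd(pct[!small], 0), trim = TRUE,
                               scientific = FALSE), " %")
  out[small] <- paste0(format(rnd(pct[small], 1), nsmall = 1, trim = TRUE,
                              scientific = FALSE), " %")
  out
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, R's default).
#'
#' @param values Non-empty numeric vector; `NA`s dropped.
#' @return Named numeric: `median`, `q1`, `q3`.
#' @export
#' @examples
#' median_iqr(1:5)  # 3, 2, 4
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty value list")
  c(median = median(values),
    q1 = unname(quantile(values, 0.25, type = 7)),
    q3 = unname(quantile(values, 0.75, type = 7)))
}

#' Frequency table over a classification
#'
#' Counts per class with rendered percents of a stated denominator. For a
#' multi-valued classification (a list of code vectors, e.g. distribution-
#' assessment codes) a record counts once for each code it carries, so
#' column sums may exceed the denominator.
#'
#' @param x Factor/character vector (single-valued) or list of character
#'   vectors (multi-valued).
#' @param levels Row order; defaults to factor levels or sorted unique
#'   values. Levels absent from the data render as zero rows.
#' @param denominator Percent denominator; defaults to the number of
#'   records.
#' @param title Table title.
#' @param mode Rounding mode for [render_percent()].
#' @return An `audit_table` (tibble of `label`, `count`, `percent`,
#'   `rendered` plus `title` and `denominator` attributes).
#' @export
frequency_table <- function(x, levels = NULL, denominator = NULL,
                            title = "", mode = "half-away") {
  n_records <- if (is.list(x)) length(x) else length(x)
  if (is.null(denominator)) denominator <- n_records
  if (denominator <= 0) stop("denominator must be > 0")
  flat <- if (is.list(x)) unlist(x, use.names = FALSE) else as.character(x)
  if (is.null(levels)) {
    levels <- if (is.factor(x)) base::levels(x) else sort(unique(flat))
  }
  counts <- table(factor(flat, levels = levels))
  data <- tibble::tibble(
    label = levels,
    count = as.integer(counts),
    percent = 100 * as.integer(counts) / denominator,
    rendered = render_percent(as.integer(counts), denominator, mode)
  )
  structure(list(title = title, kind = "frequency", data = data,
                 denominator = denominator),
            class = "audit_table")
}

#' Cross-tabulation with row- or column-wise percents
#'
#' Cell counts of two classifications with percents along a chosen axis —
#' the convention the published tables mix (weighted-mean x follow-up uses
#' row percents; ratio x follow-up uses column percents), so the axis is
#' always explicit. Records unclassified on either axis are dropped.
#'
#' @param rows,cols Factors (or vectors coerced via the corresponding
#'   `*_levels` arguments).
#' @param percent_axis `"row"` or `"col"`.
#' @param row_levels,col_levels Level orders; default to factor levels.
#' @param title Table title.
#' @param mode Rounding mode for [render_percent()].
#' @return An `audit_table` with `counts`, `percents`, and `rendered`
#'   matrices (rendered cells are `"n (p %)"`, bare `"0"` for empty cells),
#'   plus row/column totals.
#' @export
crosstab <- function(rows, cols, percent_axis = c("row", "col"),
                     row_levels = NULL, col_levels = NULL, title = "",
                     mode = "half-away") {
  percent_axis <- match.arg(percent_axis)
  if (is.null(row_levels)) {
    row_levels <- if (is.factor(rows)) levels(rows) else sort(unique(rows))
  }
  if (is.null(col_levels)) {
    col_levels <- if (is.factor(cols)) levels(cols) else sort(unique(cols))
  }
  if (length(row_levels) == 0 || length(col_levels) == 0) {
    stop("empty classification axis")
  }
  keep <- !is.na(rows) & !is.na(cols)
  counts <- table(factor(rows[keep], levels = row_levels),
                  factor(cols[keep], levels = col_levels))
  counts <- matrix(as.integer(counts), nrow = length(row_levels),
                   dimnames = list(row_levels, col_levels))
  margin <- if (percent_axis == "row") rowSums(counts) else colSums(counts)
  denom <- if (percent_axis == "row") {
    matrix(margin, nrow(counts), ncol(counts))
  } else {
    matrix(margin, nrow(counts), ncol(counts), byrow = TRUE)
  }
  percents <- ifelse(denom > 0, 100 * counts / denom, NA_real_)
  dimnames(percents) <- dimnames(counts)
  rendered <- matrix("0", nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
  nz <- counts > 0 & denom > 0
  rendered[nz] <- paste0(counts[nz], " (",
                         render_percent(counts[nz], denom[nz], mode), ")")
  structure(list(title = title, kind = "crosstab", counts = counts,
                 percents = percents, rendered = rendered,
                 percent_axis = percent_axis,
                 row_totals = rowSums(counts), col_totals = colSums(counts),
                 denominator = sum(counts)),
            class = "audit_table")
}

#' @export
print.audit_table <- function(x, ...) {
  if (nzchar(x$title)) cat(x$title, "\n")
  if (x$kind == "frequency") {
    cat("n =", x$denominator, "\n")
    df <- as.data.frame(x$data[, c("label", "count", "rendered")])
    print(df, row.names = FALSE)
  } else {
    cat("percents per", x$percent_axis, "; n =", x$denominator, "\n")
    print(as.data.frame(x$rendered))
  }
  invisible(x)
}

#' Flatten an audit table to a tibble for CSV export
#'
#' @param x An `audit_table`.
#' @param ... Unused.
#' @return Tibble: frequency tables as label/count/percent/rendered rows,
#'   cross-tabs in long form (row, col, count, percent, rendered).
#' @export
as_tibble_audit <- function(x, ...) {
  stopifnot(inherits(x, "audit_table"))
  if (x$kind == "frequency") return(x$data)
  idx <- expand.grid(row = rownames(x$counts), col = colnames(x$counts),
                     stringsAsFactors = FALSE)
  tibble::tibble(
    row = idx$row, col = idx$col,
    count = as.integer(x$counts[cbind(idx$row, idx$col)]),
    percent = as.numeric(x$percents[cbind(idx$row, idx$col)]),
    rendered = x$rendered[cbind(idx$row, idx$col)]
  )
}

# markdown rendering used by the combined audit report
.audit_table_md <- function(x) {
  if (x$kind == "frequency") {
    lines <- c(paste0("### ", x$title),
               paste0("(n = ", x$denominator, ")"), "",
               "| Category | Number (%) |", "| --- | --- |",
               paste0("| ", x$data$label, " | ", x$data$count, " (",
                      x$data$rendered, ") |"))
  } else {
    head <- paste0("| | ", paste(colnames(x$rendered), collapse = " | "),
                   " | Total |")
    sep <- paste0("| --- |",
                  paste(rep(" --- |", ncol(x$rendered) + 1), collapse = ""))
    body <- vapply(seq_len(nrow(x$rendered)), function(i) {
      paste0("| ", rownames(x$rendered)[i], " | ",
             paste(x$rendered[i, ], collapse = " | "), " | ",
             x$row_totals[i], " |")
    }, character(1))
    lines <- c(paste0("### ", x$title),
               paste0("(n = ", x$denominator, "; percents per ",
                      x$percent_axis, ")"), "", head, sep, body)
  }
  c(lines, "")
}
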