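# End-to-end audit: per-trial derived columns, the four report tables,
# run manifests, and the generate/audit entry points.

#' Per-trial audit of a validated registry
#'
#' Runs the full derivation chain on every record: pooled variability
#' ([pooled_summary()]), PROM-scale normalization and crossover flags,
#' observed and estimated effect sizes and their ratio, and the follow-up /
#' mean-percent / ratio bins the report tables use.
#'
#' Eligibility columns:
#' \describe{
#'   \item{scaled_eligible}{both arms summarised and a bounded scale
#'     present — the denominator of the mean-percent cross-tab.}
#'   \item{ratio_eligible}{summaries recoverable, a positive pooled SD,
#'     and a complete power calculation (MD and SD estimates) — the
#'     denominator of the ratio cross-tab.}
#' }
#' A record whose native mean falls outside its scale bounds (an
#' extraction mistake) is dropped from the scaled analysis with a warning,
#' never silently clipped.
#'
#' @param records Validated registry tibble (from [read_registry()],
#'   [validate_records()] or [generate_registry()]).
#' @param k Crossover multiplier: flag when mean + k SD > 100%. Default 1.
#' @param scheme Follow-up binning scheme, see [bin_followup()].
#' @param ci_method CI inversion divisor, see [sd_from_ci()].
#' @param include_floor Also compute the symmetric floor flag
#'   (mean - k SD < 0). Off by default.
#' @return Tibble, one row per record, with identifiers, eligibility
#'   flags, `n_total`, `weighted_mean`, `sd_pooled`, `sd_source`,
#'   `mean_pct`, `sd_pct`, `crossover_flag`, `tail_frac`, `d_obs`,
#'   `d_est`, `ratio`, and the three bin columns.
#' @export
audit_registry <- function(records, k = 1, scheme = c("quarters", "nine"),
                           ci_method = "auto", include_floor = FALSE) {
  scheme <- match.arg(scheme)
  needed <- c("has_power_calc", "has_outcome_summaries", "has_scale",
              "has_followup")
  if (!all(needed %in% names(records))) {
    records <- validate_records(records)$records
  }
  ps <- pooled_summary(records, ci_method = ci_method)

  out <- tibble::tibble(
    trial_id = records$trial_id,
    is_prom = records$is_prom,
    rationale = records$rationale,
    distribution_codes = records$distribution_codes,
    ceiling_discussed = records$ceiling_discussed,
    has_power_calc = records$has_power_calc,
    has_outcome_summaries = records$has_outcome_summaries,
    has_scale = records$has_scale,
    has_followup = records$has_followup,
    n_total = ps$n_total,
    weighted_mean = ps$weighted_mean,
    sd_pooled = ps$sd_pooled,
    sd_source = ps$source
  )
  has_sd <- !is.na(out$sd_pooled)

  scaled <- out$has_outcome_summaries & out$has_scale & has_sd
  # out-of-range native means: extraction mistakes, excluded loudly
  tol <- 1e-6 * abs(records$scale_best - records$scale_worst)
  lo <- pmin(records$scale_worst, records$scale_best)
  hi <- pmax(records$scale_worst, records$scale_best)
  oor <- scaled & (out$weighted_mean < lo - tol | out$weighted_mean > hi + tol)
  oor[is.na(oor)] <- FALSE
  if (any(oor)) {
    warning(sum(oor), " record(s) with weighted mean outside the scale ",
            "bounds excluded from the scaled analysis: ",
            paste(utils::head(out$trial_id[oor], 5), collapse = ", "))
    scaled <- scaled & !oor
  }
  out$scaled_eligible <- scaled

  out$mean_pct <- NA_real_
  out$sd_pct <- NA_real_
  if (any(scaled)) {
    out$mean_pct[scaled] <- to_scale_percent(
      out$weighted_mean[scaled], records$scale_worst[scaled],
      records$scale_best[scaled])
    out$sd_pct[scaled] <- sd_to_percent(
      out$sd_pooled[scaled], records$scale_worst[scaled],
      records$scale_best[scaled])
  }
  out$crossover_flag <- ceiling_crossover(out$mean_pct, out$sd_pct, k)
  if (include_floor) {
    out$floor_flag <- floor_crossover(out$mean_pct, out$sd_pct, k)
  }
  out$tail_frac <- ifelse(out$scaled_eligible,
                          tail_beyond_ceiling(out$mean_pct, out$sd_pct),
                          NA_real_)

  md_obs <- abs(records$mean_a - records$mean_b)
  out$d_obs <- ifelse(out$has_outcome_summaries & has_sd & ps$sd_pooled > 0,
                      md_obs / ps$sd_pooled, NA_real_)
  out$d_est <- estimated_effect_size(records$md_est, records$sd_est)
  out$ratio_eligible <- !is.na(out$d_obs) & !is.na(out$d_est) & out$d_est > 0
  out$ratio <- ifelse(out$ratio_eligible, out$d_obs / out$d_est, NA_real_)

  out$followup_bin <- bin_followup(records$followup_days,
                                   records$followup_na, scheme)
  out$mean_pct_bin <- bin_mean_pct(out$mean_pct)
  out$ratio_bin <- bin_ratio(out$ratio)
  out
}

#' The four audit report tables
#'
#' Builds the report tables a trial audit publishes from a per-trial audit
#' tibble ([audit_registry()] output):
#' \describe{
#'   \item{rationale}{frequency of MD-estimate rationale codes over all
#'     records (plus a none/provided summary pair).}
#'   \item{distribution}{frequency of distribution-assessment codes;
#'     multi-coded trials count once per code.}
#'   \item{mean_by_followup}{weighted-mean percent bins x follow-up bins
#'     on scale-eligible trials, row-wise percents.}
#'   \item{ratio_by_followup}{effect-size-ratio bins x follow-up bins on
#'     ratio-eligible trials, column-wise percents, plus a median (IQR)
#'     tibble per follow-up column and overall.}
#' }
#'
#' @param audit Per-trial audit tibble.
#' @param mode Percent-rounding mode (see [render_percent()]).
#' @param percent_axis_mean,percent_axis_ratio Override the per-table
#'   percent axis conventions.
#' @return Named list of `audit_table`s; `ratio_medians` is a plain tibble.
#' @export
audit_report_tables <- function(audit, mode = "half-away",
                                percent_axis_mean = "row",
                                percent_axis_ratio = "col") {
  n <- nrow(audit)
  provided <- audit$rationale != "NONE"
  rationale_tab <- frequency_table(
    factor(audit$rationale, levels = rationale_codes()),
    denominator = n, mode = mode,
    title = "Rationale or reference provided for the MD estimate used in power calculation")
  summary_tab <- frequency_table(
    factor(ifelse(provided, "PROVIDED", "NONE"),
           levels = c("NONE", "PROVIDED")),
    denominator = n, mode = mode,
    title = "Any rationale or reference provided")

  codes <- strsplit(audit$distribution_codes, ";", fixed = TRUE)
  codes <- lapply(codes, function(x) x[x != ""])
  dist_tab <- frequency_table(
    codes, levels = distribution_codes(), denominator = n, mode = mode,
    title = "Distributional assessments of the primary outcome")

  scaled <- audit[audit$scaled_eligible %in% TRUE, , drop = FALSE]
  mean_tab <- crosstab(
    scaled$mean_pct_bin, scaled$followup_bin,
    percent_axis = percent_axis_mean, mode = mode,
    row_levels = mean_pct_levels(),
    col_levels = levels(audit$followup_bin),
    title = "Weighted mean in percent of the best score, by follow-up")

  rat <- audit[audit$ratio_eligible %in% TRUE, , drop = FALSE]
  ratio_tab <- crosstab(
    rat$ratio_bin, rat$followup_bin,
    percent_axis = percent_axis_ratio, mode = mode,
    row_levels = ratio_levels(),
    col_levels = levels(audit$followup_bin),
    title = "Ratio of observed to estimated effect size, by follow-up")

  med_rows <- lapply(levels(audit$followup_bin), function(lv) {
    v <- rat$ratio[rat$followup_bin == lv]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      tibble::tibble(followup = lv, n = 0L, median = NA_real_,
                     q1 = NA_real_, q3 = NA_real_)
    } else {
      m <- median_iqr(v)
      tibble::tibble(followup = lv, n = length(v), median = m[["median"]],
                     q1 = m[["q1"]], q3 = m[["q3"]])
    }
  })
  overall <- if (nrow(rat) > 0) {
    m <- median_iqr(rat$ratio)
    tibble::tibble(followup = "TOTAL", n = nrow(rat),
                   median = m[["median"]], q1 = m[["q1"]], q3 = m[["q3"]])
  } else {
    tibble::tibble(followup = "TOTAL", n = 0L, median = NA_real_,
                   q1 = NA_real_, q3 = NA_real_)
  }

  list(
    rationale_summary = summary_tab,
    rationale = rationale_tab,
    distribution = dist_tab,
    mean_by_followup = mean_tab,
    ratio_by_followup = ratio_tab,
    ratio_medians = dplyr::bind_rows(c(med_rows, list(overall)))
  )
}

#' Eligibility-chain manifest of an audit run
#'
#' Counts at each gate of the audit's eligibility chain (all records;
#' power calculation present; outcome summaries recoverable; bounded scale
#' too) plus the ratio-eligible branch. Counts along the chain are
#' non-increasing by construction.
#'
#' @param audit Per-trial audit tibble.
#' @param n_rows_read,n_rejected Ingest bookkeeping, if known.
#' @param seed,config_echo Optional provenance fields.
#' @param outputs Character vector of files the run wrote.
#' @return A `run_manifest` list, serialisable with
#'   [write_manifest()].
#' @export
run_manifest <- function(audit, n_rows_read = nrow(audit), n_rejected = 0,
                         seed = NULL, config_echo = NULL,
                         outputs = character()) {
  pw <- audit$has_power_calc %in% TRUE
  su <- pw & audit$has_outcome_summaries %in% TRUE
  sc <- su & audit$scaled_eligible %in% TRUE
  counts <- list(
    rows_read = n_rows_read,
    rejected = n_rejected,
    records = nrow(audit),
    power_calc = sum(pw),
    outcome_summaries = sum(su),
    scaled = sum(sc),
    ratio_eligible = sum(audit$ratio_eligible %in% TRUE)
  )
  structure(list(
    tool = "powergap",
    version = as.character(utils::packageVersion("powergap")),
    seed = seed,
    config = config_echo,
    counts = counts,
    outputs = outputs
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Load a run configuration from YAML or JSON
#'
#' Recognised fields: `input` (registry CSV), `out_dir`, `k` (crossover
#' multiplier), `rounding` (`"half-away"`/`"half-even"`), `scheme`
#' (follow-up bins), `seed`, and any [sim_config()] override under `sim:`.
#'
#' @param path YAML (or JSON) configuration file.
#' @return Named list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping")
  cfg
}

#' Generate a synthetic registry on disk
#'
#' Writes `registry.csv` (public extraction schema), `truths.csv` (the
#' latent truth channel, kept separate on purpose), and `manifest.json`
#' into `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()], or a path to a YAML file whose `sim:`
#'   mapping overrides the defaults; `NULL` for the defaults.
#' @param seed Optional master-seed override.
#' @return The run manifest, invisibly.
#' @export
cmd_generate <- function(out_dir, config = NULL, seed = NULL) {
  if (is.character(config)) {
    raw <- load_run_config(config)
    sim_over <- if (!is.null(raw$sim)) raw$sim else list()
    if (!is.null(raw$seed) && is.null(seed)) seed <- raw$seed
    config <- do.call(sim_config, sim_over)
  } else if (is.null(config)) {
    config <- sim_config()
  }
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  gen <- generate_registry(config)
  if (config$n_trials == 0) warning("n_trials = 0: header-only registry")
  reg_path <- file.path(out_dir, "registry.csv")
  truth_path <- file.path(out_dir, "truths.csv")
  write_registry(gen$records, reg_path)
  readr::write_csv(gen$truths, truth_path, na = "", progress = FALSE)

  audit <- audit_registry(gen$records)
  manifest <- run_manifest(
    audit, n_rows_read = config$n_trials, n_rejected = 0,
    seed = config$seed,
    config_echo = list(n_trials = config$n_trials),
    outputs = c("registry.csv", "truths.csv", "manifest.json"))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Audit a registry on disk
#'
#' Reads and validates a registry CSV, derives the per-trial audit columns,
#' and writes `audit.csv`, one CSV per report table
#' (`table_rationale.csv`, `table_distribution.csv`,
#' `table_mean_by_followup.csv`, `table_ratio_by_followup.csv`,
#' `table_ratio_medians.csv`), a combined Markdown report (`report.md`),
#' and `manifest.json`. Empty eligible sets yield empty tables with a
#' warning, not an error. Reruns on the same input are byte-identical.
#'
#' @param registry Path to a registry CSV, or an already-validated
#'   registry tibble.
#' @param out_dir Output directory (created if needed).
#' @param k Crossover multiplier (default 1).
#' @param scheme Follow-up binning scheme.
#' @param mode Percent-rounding mode.
#' @param percent_axis_mean,percent_axis_ratio Per-table percent-axis
#'   overrides (defaults: row-wise for the mean table, column-wise for the
#'   ratio table).
#' @return List with `audit`, `tables`, `manifest`, invisibly.
#' @export
cmd_audit <- function(registry, out_dir, k = 1,
                      scheme = c("quarters", "nine"), mode = "half-away",
                      percent_axis_mean = "row", percent_axis_ratio = "col") {
  scheme <- match.arg(scheme)
  if (is.character(registry)) {
    ing <- read_registry(registry)
    records <- ing$records
    n_rows <- nrow(ing$records) + nrow(ing$rejections)
    n_rej <- nrow(ing$rejections)
    if (n_rej > 0) {
      warning("rejected ", n_rej, " row(s): ",
              paste(unique(ing$rejections$reason), collapse = ", "))
    }
  } else {
    records <- registry
    if (!"has_power_calc" %in% names(records)) {
      records <- validate_records(records)$records
    }
    n_rows <- nrow(records)
    n_rej <- 0
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  audit <- audit_registry(records, k = k, scheme = scheme)
  tables <- audit_report_tables(audit, mode = mode,
                                percent_axis_mean = percent_axis_mean,
                                percent_axis_ratio = percent_axis_ratio)
  if (sum(audit$scaled_eligible) == 0) {
    warning("no scale-eligible records: mean-by-followup table is empty")
  }
  if (sum(audit$ratio_eligible) == 0) {
    warning("no ratio-eligible records: ratio-by-followup table is empty")
  }

  outputs <- c("audit.csv", "table_rationale.csv", "table_distribution.csv",
               "table_mean_by_followup.csv", "table_ratio_by_followup.csv",
               "table_ratio_medians.csv", "report.md", "manifest.json")
  readr::write_csv(audit, file.path(out_dir, "audit.csv"), na = "",
                   progress = FALSE)
  readr::write_csv(as_tibble_audit(tables$rationale),
                   file.path(out_dir, "table_rationale.csv"),
                   progress = FALSE)
  readr::write_csv(as_tibble_audit(tables$distribution),
                   file.path(out_dir, "table_distribution.csv"),
                   progress = FALSE)
  readr::write_csv(as_tibble_audit(tables$mean_by_followup),
                   file.path(out_dir, "table_mean_by_followup.csv"),
                   progress = FALSE)
  readr::write_csv(as_tibble_audit(tables$ratio_by_followup),
                   file.path(out_dir, "table_ratio_by_followup.csv"),
                   progress = FALSE)
  readr::write_csv(tables$ratio_medians,
                   file.path(out_dir, "table_ratio_medians.csv"), na = "",
                   progress = FALSE)

  manifest <- run_manifest(audit, n_rows_read = n_rows, n_rejected = n_rej,
                           outputs = outputs)
  md <- c("# Trial audit report", "",
          paste0("Records: ", manifest$counts$records,
                 "; with power calculation: ", manifest$counts$power_calc,
                 "; with recoverable summaries: ",
                 manifest$counts$outcome_summaries,
                 "; scale-eligible: ", manifest$counts$scaled,
                 "; ratio-eligible: ", manifest$counts$ratio_eligible), "",
          .audit_table_md(tables$rationale_summary),
          .audit_table_md(tables$rationale),
          .audit_table_md(tables$distribution),
          .audit_table_md(tables$mean_by_followup),
          .audit_table_md(tables$ratio_by_followup),
          "### Median (IQR) of the effect-size ratio by follow-up", "",
          "| Follow-up | n | Median (IQR) |", "| --- | --- | --- |",
          vapply(seq_len(nrow(tables$ratio_medians)), function(i) {
            r <- tables$ratio_medians[i, ]
            md_cell <- if (is.na(r$median)) "-" else
              sprintf("%.2f (%.1f-%.1f)", r$median, r$q1, r$q3)
            paste0("| ", r$followup, " | ", r$n, " | ", md_cell, " |")
          }, character(1)))
  writeLines(md, file.path(out_dir, "report.md"))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(audit = audit, tables = tables, manifest = manifest))
}
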