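SUMMARY_SCHEMA_VERSION <- "1.0"

#' Configuration of a full pipeline run
#'
#' @param chla_path CSV of weekly chlorophyll-a observations
#'   ([read_chla_weekly()]).
#' @param smoke_path CSV of smoke densities, weekly or daily depending on
#'   `smoke_format`.
#' @param meta_path CSV of lake metadata ([read_lake_meta()]).
#' @param out_dir Output directory (created if needed).
#' @param smoke_format `"weekly"` or `"daily"`.
#' @param origin First day of week 1.
#' @param n_weeks Number of weekly bins in the study year.
#' @param seed Integer seed recorded in the run summary.
#' @param spline A [spline_config()].
#' @param strata A [strata_config()].
#' @param conversion A [conversion_params()].
#' @param mdl_filter At-MDL fraction for the event-aligned lake filter.
#' @param window_halfwidth Event window half-width (weeks).
#' @param consecutive_pattern Strict-consecutive smoke-impact pattern mode.
#' @param per_lake_mean_anova ANOVA sensitivity mode on per-lake means.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(chla_path, smoke_path, meta_path, out_dir,
                       smoke_format = c("weekly", "daily"),
                       origin = as.Date("2018-01-01"), n_weeks = 52L,
                       seed = 1L, spline = spline_config(),
                       strata = strata_config(),
                       conversion = conversion_params(),
                       mdl_filter = 0.8, window_halfwidth = 5L,
                       consecutive_pattern = FALSE,
                       per_lake_mean_anova = FALSE) {
  smoke_format <- match.arg(smoke_format)
  for (p in c(chla_path, smoke_path, meta_path))
    if (!file.exists(p)) abort_config("paths", sprintf("input does not exist: %s", p))
  structure(list(chla_path = chla_path, smoke_path = smoke_path,
                 meta_path = meta_path, out_dir = out_dir,
                 smoke_format = smoke_format, origin = as.Date(origin),
                 n_weeks = as.integer(n_weeks), seed = as.integer(seed),
                 spline = spline, strata = strata, conversion = conversion,
                 mdl_filter = mdl_filter,
                 window_halfwidth = as.integer(window_halfwidth),
                 consecutive_pattern = isTRUE(consecutive_pattern),
                 per_lake_mean_anova = isTRUE(per_lake_mean_anova)),
            class = "run_config")
}

stage_log <- function(stage, msg) {
  inform(sprintf("[%s] %s", stage, msg))
}

anova_or_note <- function(data, grouping, per_lake_mean) {
  tryCatch(residual_anova(data, grouping, value = "std_residual",
                          per_lake_mean = per_lake_mean),
           lakesmoke_contract_error = function(e) {
             warn(sprintf("ANOVA (%s) skipped: %s", grouping, conditionMessage(e)))
             NULL
           })
}

anova_json <- function(a) {
  if (is.null(a)) return(list(available = FALSE))
  list(available = TRUE, F = a$anova$F, df_between = a$anova$df_between,
       df_within = a$anova$df_within, p = a$anova$p,
       groups = as.data.frame(a$groups))
}

#' Run the full smoke / chlorophyll-a analysis pipeline
#'
#' Executes ingest, smoke-event classification, seasonal spline fitting and
#' the statistical battery in order; writes tidy CSV outputs
#' (`records.csv`, `residuals.csv`, `lake_classes.csv`, `anova_results.csv`,
#' `group_summaries.csv`, `season_ci.csv`, `event_aligned.csv`,
#' `lake_deltas.csv`, `strata_summaries.csv`) and a machine-readable
#' `summary.json` to `out_dir`. Identical inputs and configuration produce
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return The run summary (the structure written to `summary.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ingest
  chl <- read_chla_weekly(config$chla_path, config$conversion)
  if (nrow(chl) == 0L)
    abort_format(sprintf("stage ingest: chlorophyll table %s has no rows",
                         config$chla_path))
  meta <- read_lake_meta(config$meta_path)
  smoke <- if (config$smoke_format == "weekly") {
    read_smoke_weekly(config$smoke_path)
  } else {
    aggregate_smoke_daily(read_smoke_daily(config$smoke_path),
                          lake_ids = unique(chl$lake_id),
                          origin = config$origin, n_weeks = config$n_weeks)
  }
  records <- join_by_lake_week(chl, smoke, meta, origin = config$origin)
  stage_log("ingest", sprintf("%d chl rows + %d smoke rows -> %d records (%d lakes)",
                              nrow(chl), nrow(smoke), nrow(records),
                              dplyr::n_distinct(records$lake_id)))

  # smoke events
  classes <- classify_lakes(records, consecutive = config$consecutive_pattern)
  n_impacted <- sum(classes$impact_class == "smoke_impacted")
  stage_log("smoke_events", sprintf(
    "%d smoke-impacted / %d non-impacted / %d indeterminate lakes",
    n_impacted, sum(classes$impact_class == "non_impacted"),
    sum(classes$impact_class == "indeterminate")))
  windows <- extract_all_event_windows(records, classes,
                                       k = config$window_halfwidth)

  # phenology
  fits <- fit_lake_splines(records, config$spline)
  residuals <- fits$residuals
  stage_log("phenology", sprintf("%d lakes fitted, %d unfit",
                                 sum(fits$fits$converged),
                                 sum(!fits$fits$converged)))

  # statistics
  anova_smoke <- anova_or_note(residuals, "smoke_vs_no_smoke",
                               config$per_lake_mean_anova)
  anova_density <- anova_or_note(residuals, "by_density",
                                 config$per_lake_mean_anova)
  season_ci <- seasonal_smoke_difference_ci(records)
  aligned <- event_aligned_summary(windows, records,
                                   mdl_filter = config$mdl_filter)
  deltas <- per_lake_smoke_delta(residuals, classes, config$strata,
                                 value = "std_residual")
  skipped_delta <- attr(deltas, "skipped")

  baseline <- records |>
    dplyr::filter(.data$label == "no_smoke", !is.na(.data$chla)) |>
    dplyr::group_by(.data$lake_id) |>
    dplyr::summarise(baseline = mean(.data$chla), .groups = "drop")
  lake_tbl <- deltas |>
    dplyr::left_join(baseline, by = "lake_id") |>
    dplyr::left_join(meta[, c("lake_id", "elevation")], by = "lake_id")
  lake_tbl$trophic <- classify_trophic(lake_tbl$baseline,
                                       config$strata$trophic_breaks)
  lake_tbl$elev_class <- classify_elevation(lake_tbl$elevation,
                                            config$strata$elevation_breaks)
  # impact stratum: delta for smoke-impacted lakes, mean residual for
  # non-impacted lakes (a delta is undefined without smoke weeks)
  non_imp <- classes$lake_id[classes$impact_class == "non_impacted"]
  non_imp_resid <- residuals |>
    dplyr::filter(.data$lake_id %in% non_imp, !is.na(.data$std_residual)) |>
    dplyr::group_by(.data$lake_id) |>
    dplyr::summarise(value = mean(.data$std_residual), .groups = "drop")
  impact_tbl <- dplyr::bind_rows(
    tibble::tibble(lake_id = lake_tbl$lake_id, value = lake_tbl$delta,
                   class = "smoke_impacted"),
    tibble::tibble(lake_id = non_imp_resid$lake_id,
                   value = non_imp_resid$value, class = "non_impacted"))
  strata_sum <- dplyr::bind_rows(
    dplyr::mutate(stratified_residual_summary(impact_tbl, "class", "value",
                  levels = c("smoke_impacted", "non_impacted")),
                  stratification = "impact", .before = 1),
    dplyr::mutate(stratified_residual_summary(lake_tbl, "trophic", "delta",
                  levels = c("oligotrophic", "mesotrophic", "eutrophic")),
                  stratification = "trophic", .before = 1),
    dplyr::mutate(stratified_residual_summary(lake_tbl, "elev_class", "delta",
                  levels = c("lower", "medium", "higher")),
                  stratification = "elevation", .before = 1))
  stage_log("bloom_stats", sprintf(
    "%d lake deltas (%d skipped), %d event windows", nrow(deltas),
    nrow(skipped_delta), dplyr::n_distinct(windows$anchor_week)))

  # outputs
  out <- function(f) file.path(config$out_dir, f)
  readr::write_csv(records, out("records.csv"))
  readr::write_csv(residuals, out("residuals.csv"))
  readr::write_csv(classes, out("lake_classes.csv"))
  anova_tbl <- dplyr::bind_rows(
    if (!is.null(anova_smoke)) dplyr::mutate(anova_smoke$anova, grouping = "smoke_vs_no_smoke", .before = 1),
    if (!is.null(anova_density)) dplyr::mutate(anova_density$anova, grouping = "by_density", .before = 1))
  group_tbl <- dplyr::bind_rows(
    if (!is.null(anova_smoke)) dplyr::mutate(anova_smoke$groups, grouping = "smoke_vs_no_smoke", .before = 1),
    if (!is.null(anova_density)) dplyr::mutate(anova_density$groups, grouping = "by_density", .before = 1))
  readr::write_csv(anova_tbl, out("anova_results.csv"))
  readr::write_csv(group_tbl, out("group_summaries.csv"))
  readr::write_csv(season_ci, out("season_ci.csv"))
  readr::write_csv(aligned, out("event_aligned.csv"))
  readr::write_csv(deltas, out("lake_deltas.csv"))
  readr::write_csv(strata_sum, out("strata_summaries.csv"))

  bin_counts <- table(deltas$bin)
  excluded <- dplyr::bind_rows(
    tibble::tibble(lake_id = fits$fits$lake_id[!fits$fits$converged],
                   stage = "phenology", reason = "fewer than min_obs observed weeks"),
    if (nrow(skipped_delta)) dplyr::mutate(skipped_delta, stage = "bloom_stats",
                                           .after = 1))
  summary <- list(
    schema_version = SUMMARY_SCHEMA_VERSION,
    seed = config$seed,
    config = list(
      smoke_format = config$smoke_format, origin = as.character(config$origin),
      n_weeks = config$n_weeks, lambda = config$spline$lambda,
      trim = config$spline$trim, trim_mode = config$spline$trim_mode,
      min_obs = config$spline$min_obs, mdl_filter = config$mdl_filter,
      window_halfwidth = config$window_halfwidth,
      consecutive_pattern = config$consecutive_pattern,
      per_lake_mean_anova = config$per_lake_mean_anova),
    counts = list(
      lakes = dplyr::n_distinct(records$lake_id),
      records = nrow(records),
      smoke_impacted = n_impacted,
      non_impacted = sum(classes$impact_class == "non_impacted"),
      indeterminate = sum(classes$impact_class == "indeterminate"),
      lakes_fitted = sum(fits$fits$converged),
      lakes_unfit = sum(!fits$fits$converged),
      event_windows = if (nrow(windows)) dplyr::n_distinct(
        paste(windows$lake_id, windows$anchor_week)) else 0L,
      lake_deltas = nrow(deltas)),
    excluded_lakes = as.data.frame(excluded),
    anova_smoke = anova_json(anova_smoke),
    anova_density = anova_json(anova_density),
    season_ci = as.data.frame(season_ci),
    event_aligned = as.data.frame(aligned),
    delta_bins = list(bin = names(bin_counts), n = as.integer(bin_counts)),
    strata = as.data.frame(strata_sum))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(summary)
}
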