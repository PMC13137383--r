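fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "fg", flag = "#"))
}

md_table <- function(df, digits = 3) {
  cols <- names(df)
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(cols, function(c) {
      v <- df[[c]][i]
      if (is.numeric(v)) fmt_num(v, digits) else as.character(v)
    }, character(1))
    paste0("| ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(paste0("| ", paste(cols, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
    body)
}

#' Render a human-readable report of a pipeline run
#'
#' Builds a markdown report from a run summary (the list returned by
#' [run_pipeline()] or read back from its `summary.json`): run overview,
#' smoke vs no-smoke and density-class group means with significance
#' letters, seasonal difference CIs, the event-aligned composite, map bin
#' counts of per-lake deltas, and the stratified summaries.
#'
#' @param summary A run summary list, or a path to a `summary.json`.
#' @return A single markdown string (invisibly printable with `cat()`).
#' @export
render_report <- function(summary) {
  if (is.character(summary) && length(summary) == 1L)
    summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
  required <- c("schema_version", "seed", "counts", "anova_smoke",
                "anova_density", "season_ci", "event_aligned", "delta_bins",
                "strata")
  missing <- setdiff(required, names(summary))
  if (length(missing))
    abort_format(sprintf("run summary is missing field(s): %s",
                         paste(missing, collapse = ", ")))
  cn <- summary$counts
  lines <- c(
    "# Smoke / chlorophyll-a pipeline report", "",
    sprintf("Seed %s; %s lakes, %s lake-week records.", summary$seed,
            cn$lakes, cn$records),
    sprintf("Smoke-impacted: %s, non-impacted: %s, indeterminate: %s; %s lakes fitted (%s unfit).",
            cn$smoke_impacted, cn$non_impacted, cn$indeterminate,
            cn$lakes_fitted, cn$lakes_unfit), "")

  anova_section <- function(a, title) {
    if (!isTRUE(a$available))
      return(c(paste0("## ", title), "", "Not computed (degenerate grouping).", ""))
    c(paste0("## ", title), "",
      sprintf("F(%s, %s) = %s, p = %s", a$df_between, a$df_within,
              fmt_num(a$F), fmt_num(a$p)), "",
      md_table(as.data.frame(a$groups)), "")
  }
  lines <- c(lines,
    anova_section(summary$anova_smoke, "Residuals: smoke vs no smoke"),
    anova_section(summary$anova_density, "Residuals by smoke density"),
    "## Seasonal smoke / no-smoke differences (observed chlorophyll-a)", "",
    md_table(as.data.frame(summary$season_ci)), "",
    "## Event-aligned composite (week 0 = smoke event)", "",
    md_table(as.data.frame(summary$event_aligned)), "",
    "## Per-lake response delta map bins", "",
    md_table(data.frame(bin = summary$delta_bins$bin,
                        n = summary$delta_bins$n)), "",
    "## Stratified summaries", "",
    md_table(as.data.frame(summary$strata)), "")
  paste(lines, collapse = "\n")
}
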