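#' Cyanobacteria-index to chlorophyll-a conversion parameters
#'
#' The satellite product reports a dimensionless cyanobacteria index (CI);
#' surface chlorophyll-a is obtained from the power-law relation
#' `chla = offset + scale * CI^exponent`. Defaults follow the published CyAN
#' calibration (Tomlinson et al. 2016; Coffer et al. 2020):
#' chl-a (ug/L) = 6620 * CI^1.0579.
#'
#' @param scale Multiplier (ug/L per index unit), > 0.
#' @param exponent Power on the index (dimensionless).
#' @param offset Additive offset (ug/L).
#' @return A list of class `"conversion_params"`.
#' @export
conversion_params <- function(scale = 6620, exponent = 1.0579, offset = 0) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    abort_config("scale", "must be a single value > 0")
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent))
    abort_config("exponent", "must be a single finite value")
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset))
    abort_config("offset", "must be a single finite value")
  structure(list(scale = scale, exponent = exponent, offset = offset),
            class = "conversion_params")
}

#' Convert cyanobacteria index values to chlorophyll-a
#'
#' @param ci Index values (>= 0; NA passes through).
#' @param params A [conversion_params()].
#' @return Chlorophyll-a concentrations (ug/L).
#' @examples
#' ci_to_chla(3, conversion_params(scale = 2, exponent = 1, offset = 0))  # 6
#' @export
ci_to_chla <- function(ci, params = conversion_params()) {
  if (!inherits(params, "conversion_params"))
    abort_config("params", "must be created with conversion_params()")
  bad <- which(!is.na(ci) & ci < 0)
  if (length(bad))
    abort_validation(sprintf("cyanobacteria index must be >= 0 (element %d is %g)",
                             bad[1], ci[bad[1]]))
  params$offset + params$scale * ci^params$exponent
}

#' Area-normalized lake mean chlorophyll-a
#'
#' Mean over the resolved pixels of one lake-week composite: the sum of all
#' resolved pixel values divided by the number of resolved pixels. An empty
#' pixel list (no resolved pixels that week) gives NA.
#'
#' @param pixel_values Resolved pixel chlorophyll-a values (ug/L, >= 0).
#' @return A single mean (ug/L) or NA.
#' @export
area_mean_chla <- function(pixel_values) {
  if (length(pixel_values) == 0L) return(NA_real_)
  if (any(!is.finite(pixel_values)) || any(pixel_values < 0))
    abort_validation("pixel values must be finite and >= 0")
  sum(pixel_values) / length(pixel_values)
}

read_csv_quiet <- function(path, col_types) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort_format(sprintf("%s is missing required column(s): %s",
                         path, paste(missing, collapse = ", ")))
}

#' Read a weekly chlorophyll-a table
#'
#' CSV with header columns `lake_id`, `week_start`, `chla` (or `ci`),
#' `n_pixels`, `at_mdl`. A `ci` column (and no `chla`) triggers conversion
#' through [ci_to_chla()]. Weeks with zero resolved pixels carry NA
#' chlorophyll-a and are retained.
#'
#' @param path CSV path.
#' @param params [conversion_params()] used when a `ci` column is present.
#' @return Tibble of observations: `lake_id`, `week_start` (Date), `chla`,
#'   `n_pixels`, `at_mdl`.
#' @export
read_chla_weekly <- function(path, params = conversion_params()) {
  df <- read_csv_quiet(path, readr::cols(.default = readr::col_guess()))
  require_columns(df, c("lake_id", "week_start", "n_pixels", "at_mdl"), path)
  if (!"chla" %in% names(df)) {
    if (!"ci" %in% names(df))
      abort_format(sprintf("%s is missing required column(s): chla (or ci)", path))
    df$chla <- ci_to_chla(df$ci, params)
    df$ci <- NULL
  }
  bad <- which(!is.na(df$chla) & df$chla < 0)
  if (length(bad))
    abort_validation(sprintf("%s: negative chlorophyll-a in row(s) %s",
                             path, paste(utils::head(bad, 5), collapse = ", ")))
  bad_px <- which(is.na(df$n_pixels) | df$n_pixels < 0)
  if (length(bad_px))
    abort_validation(sprintf("%s: missing or negative n_pixels in row(s) %s",
                             path, paste(utils::head(bad_px, 5), collapse = ", ")))
  df$week_start <- as.Date(df$week_start)
  if (anyNA(df$week_start))
    abort_validation(sprintf("%s: unparseable week_start values", path))
  df$chla[df$n_pixels == 0L] <- NA_real_
  df$at_mdl <- as.logical(df$at_mdl)
  tibble::as_tibble(df[, c("lake_id", "week_start", "chla", "n_pixels", "at_mdl")])
}

#' Read a weekly smoke-density table
#'
#' CSV with columns `lake_id`, `week_start`, `density` in
#' `none/low/medium/high` (empty = NA, meaning the smoke record for that
#' week is missing, which is distinct from `none`).
#'
#' @param path CSV path.
#' @return Tibble: `lake_id`, `week_start` (Date), `density`.
#' @export
read_smoke_weekly <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    lake_id = readr::col_character(), week_start = readr::col_character(),
    density = readr::col_character()))
  require_columns(df, c("lake_id", "week_start", "density"), path)
  ok <- is.na(df$density) | df$density %in% c("none", "low", "medium", "high")
  if (!all(ok))
    abort_validation(sprintf("%s: unknown density value(s): %s", path,
                             paste(unique(df$density[!ok]), collapse = ", ")))
  df$week_start <- as.Date(df$week_start)
  tibble::as_tibble(df)
}

#' Read a daily smoke-density table
#'
#' CSV with columns `lake_id`, `date`, `density` in `low/medium/high` (rows
#' exist only for days when a plume overlapped the lake; a row with empty
#' density marks a day with a missing smoke record).
#'
#' @param path CSV path.
#' @return Tibble: `lake_id`, `date` (Date), `density`.
#' @export
read_smoke_daily <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    lake_id = readr::col_character(), date = readr::col_character(),
    density = readr::col_character()))
  require_columns(df, c("lake_id", "date", "density"), path)
  ok <- is.na(df$density) | df$density %in% c("low", "medium", "high")
  if (!all(ok))
    abort_validation(sprintf("%s: unknown density value(s): %s", path,
                             paste(unique(df$density[!ok]), collapse = ", ")))
  df$date <- as.Date(df$date)
  tibble::as_tibble(df)
}

#' Read a lake metadata table
#'
#' CSV with columns `lake_id`, `lat`, `lon`, `elevation` and optionally
#' `area`, `name`. Missing elevations are retained as NA.
#'
#' @param path CSV path.
#' @return Tibble of lake metadata.
#' @export
read_lake_meta <- function(path) {
  df <- read_csv_quiet(path, readr::cols(.default = readr::col_guess()))
  require_columns(df, c("lake_id", "lat", "lon", "elevation"), path)
  if (anyDuplicated(df$lake_id))
    abort_validation(sprintf("%s: duplicated lake_id values", path))
  if (any(!is.na(df$lat) & abs(df$lat) > 90))
    abort_validation(sprintf("%s: latitude outside [-90, 90]", path))
  if (any(!is.na(df$lon) & abs(df$lon) > 180))
    abort_validation(sprintf("%s: longitude outside [-180, 180]", path))
  tibble::as_tibble(df)
}

#' Join chlorophyll-a, smoke and metadata into analysis rows
#'
#' Full outer join on (`lake_id`, `week_start`). A lake-week present in the
#' chlorophyll table but absent from the smoke table is treated as having no
#' recorded plume (`density = "none"`); an explicit NA density in the smoke
#' table stays NA (missing smoke record). Labels follow the event
#' definitions: `smoke` iff density is low/medium/high, `no_smoke` iff
#' density is none, NA iff density is NA.
#'
#' @param chl Tibble from [read_chla_weekly()].
#' @param smoke Tibble from [read_smoke_weekly()] (may have zero rows).
#' @param meta Optional tibble from [read_lake_meta()]; when given, metadata
#'   columns are carried onto each row.
#' @param origin First day of week 1, for `week_index`.
#' @return Tibble of lake-week records: `lake_id`, `week_index`,
#'   `week_start`, `chla`, `n_pixels`, `at_mdl`, `density`, `label` (plus
#'   metadata columns).
#' @export
join_by_lake_week <- function(chl, smoke, meta = NULL,
                              origin = as.Date("2018-01-01")) {
  key_chl <- paste(chl$lake_id, chl$week_start)
  if (anyDuplicated(key_chl))
    abort_validation("duplicate (lake_id, week_start) rows in chlorophyll table")
  if (nrow(smoke)) {
    key_smk <- paste(smoke$lake_id, smoke$week_start)
    if (anyDuplicated(key_smk))
      abort_validation("duplicate (lake_id, week_start) rows in smoke table")
  }
  out <- dplyr::full_join(chl, smoke, by = c("lake_id", "week_start"))
  # absent smoke row = no plume recorded; explicit NA density stays NA
  if (!"density" %in% names(out)) out$density <- "none"
  key_smoke <- if (nrow(smoke)) paste(smoke$lake_id, smoke$week_start) else character()
  absent <- !(paste(out$lake_id, out$week_start) %in% key_smoke)
  out$density[absent] <- "none"
  out$label <- label_lake_weeks(out$density)
  out$week_index <- week_index(out$week_start, origin)
  if (!is.null(meta)) out <- dplyr::left_join(out, meta, by = "lake_id")
  cols <- c("lake_id", "week_index", "week_start", "chla", "n_pixels",
            "at_mdl", "density", "label")
  out <- dplyr::arrange(out, .data$lake_id, .data$week_index)
  out[, c(cols, setdiff(names(out), cols))]
}
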