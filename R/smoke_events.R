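DENSITY_LEVELS <- c("low", "medium", "high")
DENSITY_VALUES <- c(low = 5, medium = 16, high = 27)  # ug/m^3, HMS convention

#' Numeric value of a smoke density category
#'
#' The Hazard Mapping System convention assigns 5, 16 and 27 ug/m^3 to low-,
#' medium- and high-density smoke; the ordering low < medium < high drives
#' all maximum-density compositing.
#'
#' @param category Character vector over `c("low","medium","high")`.
#' @return Numeric ug/m^3 values.
#' @export
density_value <- function(category) {
  bad <- !is.na(category) & !category %in% DENSITY_LEVELS
  if (any(bad))
    abort_validation(sprintf("unknown smoke density category: %s",
                             paste(unique(category[bad]), collapse = ", ")))
  unname(DENSITY_VALUES[category])
}

#' Resolve overlapping plume densities for one lake-day
#'
#' Where several plume polygons overlap a lake on the same day, the highest
#' density is kept.
#'
#' @param densities Character vector of categories over the lake that day
#'   (possibly empty).
#' @return One of `"low"/"medium"/"high"`, or `"none"` for an empty list.
#' @export
resolve_daily_density <- function(densities) {
  densities <- densities[!is.na(densities)]
  if (length(densities) == 0L) return("none")
  DENSITY_LEVELS[max(match_density(densities))]
}

match_density <- function(x) {
  m <- match(x, DENSITY_LEVELS)
  if (anyNA(m))
    abort_validation(sprintf("unknown smoke density category: %s",
                             paste(unique(x[is.na(m)]), collapse = ", ")))
  m
}

#' Composite daily densities into a weekly value
#'
#' Preserves the highest smoke density over the (up to) 7 days of one weekly
#' bin: the maximum over non-missing days; `"none"` if all non-missing days
#' have no plume; NA if every day is missing.
#'
#' @param daily Character vector (1-7 values) over
#'   `c("none","low","medium","high")`; NA marks a missing day.
#' @return One of `"none"/"low"/"medium"/"high"` or NA.
#' @export
composite_weekly_density <- function(daily) {
  if (length(daily) < 1L || length(daily) > 7L)
    abort_validation(sprintf("a weekly bin has 1-7 days, got %d", length(daily)))
  obs <- daily[!is.na(daily)]
  if (length(obs) == 0L) return(NA_character_)
  smoke <- obs[obs != "none"]
  if (length(smoke) == 0L) return("none")
  DENSITY_LEVELS[max(match_density(smoke))]
}

#' Aggregate a daily smoke table to weekly maxima
#'
#' Expands each lake's daily record over the full span of weekly bins (days
#' without a row carry no plume), resolves within-day overlaps to the
#' highest density, then composites each 7-day bin to its maximum density.
#' A day recorded with NA density is a missing observation; a week whose
#' days are all missing is NA.
#'
#' @param daily Tibble from [read_smoke_daily()].
#' @param lake_ids Lakes to aggregate (defaults to those present in `daily`).
#' @param origin First day of week 1.
#' @param n_weeks Number of weekly bins to emit per lake.
#' @return Tibble: `lake_id`, `week_start`, `density`.
#' @export
aggregate_smoke_daily <- function(daily, lake_ids = NULL,
                                  origin = as.Date("2018-01-01"),
                                  n_weeks = 52L) {
  lake_ids <- lake_ids %||% sort(unique(daily$lake_id))
  all_days <- seq(origin, by = 1, length.out = 7L * n_weeks)
  out <- vector("list", length(lake_ids))
  for (i in seq_along(lake_ids)) {
    rows <- daily[daily$lake_id == lake_ids[i], ]
    # resolve within-day polygon overlap to the highest density
    day_max <- rep("none", length(all_days))
    if (nrow(rows)) {
      for (d in unique(rows$date)) {
        j <- which(all_days == d)
        if (!length(j)) next
        vals <- rows$density[rows$date == d]
        day_max[j] <- if (all(is.na(vals))) NA_character_ else
          resolve_daily_density(vals)
      }
    }
    wk <- vapply(seq_len(n_weeks), function(w)
      composite_weekly_density(day_max[(7L * (w - 1L) + 1L):(7L * w)]),
      character(1))
    out[[i]] <- tibble::tibble(lake_id = lake_ids[i],
                               week_start = week_start(seq_len(n_weeks), origin),
                               density = wk)
  }
  dplyr::bind_rows(out)
}

#' Label lake-weeks as smoke / no-smoke events
#'
#' A smoke event is any week in which a plume was detected over the lake
#' (density low/medium/high); a no-smoke event is a week with a record and
#' no plume; weeks with a missing smoke record stay NA.
#'
#' @param density Character vector over `c("none","low","medium","high")`
#'   (NA allowed).
#' @return Character vector over `c("smoke","no_smoke")` with NAs preserved.
#' @export
label_lake_weeks <- function(density) {
  if (length(density) == 0L) return(character())
  ok <- is.na(density) | density %in% c("none", DENSITY_LEVELS)
  if (!all(ok))
    abort_validation(sprintf("unknown smoke density category: %s",
                             paste(unique(density[!ok]), collapse = ", ")))
  ifelse(is.na(density), NA_character_,
         ifelse(density == "none", "no_smoke", "smoke"))
}

#' Classify a lake's smoke-impact pattern
#'
#' A lake-year is `smoke_impacted` if its label sequence contains a no-smoke
#' week, later a smoke week, and later again a no-smoke week (NA weeks are
#' skipped, order preserved). It is `non_impacted` if it has zero smoke
#' weeks and at least `min_clear_weeks` no-smoke weeks. Anything else is
#' `indeterminate`.
#'
#' With `consecutive = TRUE` the no-smoke / smoke / no-smoke pattern must be
#' contiguous in the observed (NA-dropped) sequence: a complete run of smoke
#' weeks immediately flanked by no-smoke weeks.
#'
#' @param labels Character vector over `c("smoke","no_smoke")` with NAs.
#' @param min_clear_weeks No-smoke weeks needed to call a smoke-free lake
#'   non-impacted (default 6).
#' @param consecutive Require the pattern to be contiguous (default FALSE,
#'   the ordered-subsequence reading).
#' @return One of `"smoke_impacted"`, `"non_impacted"`, `"indeterminate"`.
#' @export
classify_lake <- function(labels, min_clear_weeks = 6L, consecutive = FALSE) {
  obs <- labels[!is.na(labels)]
  if (!all(obs %in% c("smoke", "no_smoke")))
    abort_validation("labels must be 'smoke', 'no_smoke' or NA")
  if (!any(obs == "smoke")) {
    if (sum(obs == "no_smoke") >= min_clear_weeks) return("non_impacted")
    return("indeterminate")
  }
  if (!consecutive) {
    first_clear <- match("no_smoke", obs)
    if (!is.na(first_clear)) {
      smoke_after <- which(obs == "smoke" & seq_along(obs) > first_clear)
      if (length(smoke_after) &&
          any(obs == "no_smoke" & seq_along(obs) > smoke_after[1]))
        return("smoke_impacted")
    }
    return("indeterminate")
  }
  # runs alternate smoke / no_smoke, so an interior smoke run is flanked by
  # no-smoke weeks on both sides
  r <- rle(obs)
  for (k in seq_along(r$values)) {
    if (r$values[k] == "smoke" && k > 1L && k < length(r$values))
      return("smoke_impacted")
  }
  "indeterminate"
}

#' Classify every lake in a record table
#'
#' @param records Lake-week records (needs `lake_id`, `label`), one row per
#'   lake-week.
#' @param ... Passed to [classify_lake()].
#' @return Tibble: `lake_id`, `impact_class`.
#' @export
classify_lakes <- function(records, ...) {
  records |>
    dplyr::arrange(.data$lake_id, .data$week_index) |>
    dplyr::group_by(.data$lake_id) |>
    dplyr::summarise(impact_class = classify_lake(.data$label, ...),
                     .groups = "drop")
}

smoke_runs <- function(labels) {
  is_smoke <- !is.na(labels) & labels == "smoke"
  r <- rle(is_smoke)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts[r$values]
}

#' Extract event-aligned windows around smoke events
#'
#' Each maximal run of consecutive smoke weeks yields one window anchored at
#' the run's first week (relative week 0); consecutive smoke weeks of the
#' same run appear at relative weeks +1, +2, ... rather than as separate
#' events. Windows span relative weeks -k..+k, truncated at the series
#' boundaries.
#'
#' @param labels Weekly labels for one lake (`smoke`/`no_smoke`/NA).
#' @param chla Weekly chlorophyll-a values, same length.
#' @param at_mdl Weekly at-detection-limit flags, same length (optional).
#' @param k Window half-width in weeks (default 5).
#' @param lake_id Identifier carried into the output.
#' @param week_index Week indices (defaults to positions).
#' @return Tibble: `lake_id`, `anchor_week`, `relative_week`, `week_index`,
#'   `chla`, `at_mdl`, `label`.
#' @export
extract_event_windows <- function(labels, chla, at_mdl = NULL, k = 5L,
                                  lake_id = NA_character_,
                                  week_index = seq_along(labels)) {
  if (classify_lake(labels) != "smoke_impacted")
    abort_contract("event windows are only defined for smoke-impacted lakes")
  stopifnot(length(chla) == length(labels))
  at_mdl <- at_mdl %||% rep(NA, length(labels))
  anchors <- smoke_runs(labels)
  out <- lapply(anchors, function(a) {
    rel <- -k:k
    idx <- a + rel
    keep <- idx >= 1L & idx <= length(labels)
    tibble::tibble(lake_id = lake_id, anchor_week = week_index[a],
                   relative_week = rel[keep], week_index = week_index[idx[keep]],
                   chla = chla[idx[keep]], at_mdl = at_mdl[idx[keep]],
                   label = labels[idx[keep]])
  })
  dplyr::bind_rows(out)
}

#' Extract event windows for all smoke-impacted lakes in a record table
#'
#' @param records Lake-week records (needs `lake_id`, `week_index`, `label`,
#'   `chla`, `at_mdl`).
#' @param classes Optional tibble from [classify_lakes()] (recomputed if
#'   missing).
#' @param k Window half-width in weeks.
#' @return Tibble of windows across lakes (zero rows if no lake qualifies).
#' @export
extract_all_event_windows <- function(records, classes = NULL, k = 5L) {
  classes <- classes %||% classify_lakes(records)
  impacted <- classes$lake_id[classes$impact_class == "smoke_impacted"]
  records <- dplyr::arrange(records, .data$lake_id, .data$week_index)
  out <- lapply(impacted, function(id) {
    r <- records[records$lake_id == id, ]
    extract_event_windows(r$label, r$chla, r$at_mdl, k = k, lake_id = id,
                          week_index = r$week_index)
  })
  if (!length(out))
    return(tibble::tibble(lake_id = character(), anchor_week = integer(),
                          relative_week = integer(), week_index = integer(),
                          chla = numeric(), at_mdl = logical(),
                          label = character()))
  dplyr::bind_rows(out)
}
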