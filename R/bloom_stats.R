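#' Stratification thresholds and map bin edges
#'
#' Trophic status follows EPA chlorophyll-a guidelines (oligotrophic < 2,
#' mesotrophic 2-7, eutrophic > 7 ug/L; boundaries belong to mesotrophic).
#' Elevation classes follow the lowest / middle-two / highest quartiles of
#' the smoke-impacted lake population (2018 CONUS values 255 and 538 m;
#' boundaries belong to the medium class; recompute with
#' [elevation_bounds()]). Map bins partition per-lake response deltas.
#'
#' @param trophic_breaks Chlorophyll-a thresholds (ug/L), increasing.
#' @param elevation_breaks Elevation thresholds (m), increasing.
#' @param delta_bin_edges Right-closed bin edges (ug/L) partitioning the
#'   real line, first `-Inf`, last `Inf`.
#' @return A list of class `"strata_config"`.
#' @export
strata_config <- function(trophic_breaks = c(2, 7),
                          elevation_breaks = c(255, 538),
                          delta_bin_edges = c(-Inf, -10, -5, -3, -1, 0,
                                              1, 3, 5, 10, Inf)) {
  if (!is.numeric(trophic_breaks) || length(trophic_breaks) != 2L ||
      diff(trophic_breaks) <= 0)
    abort_config("trophic_breaks", "must be two strictly increasing thresholds")
  if (!is.numeric(elevation_breaks) || length(elevation_breaks) != 2L ||
      diff(elevation_breaks) <= 0)
    abort_config("elevation_breaks", "must be two strictly increasing thresholds")
  if (!is.numeric(delta_bin_edges) || is.unsorted(delta_bin_edges, strictly = TRUE) ||
      delta_bin_edges[1] != -Inf || delta_bin_edges[length(delta_bin_edges)] != Inf)
    abort_config("delta_bin_edges", "must strictly increase from -Inf to Inf")
  structure(list(trophic_breaks = trophic_breaks,
                 elevation_breaks = elevation_breaks,
                 delta_bin_edges = delta_bin_edges),
            class = "strata_config")
}

group_summary_tbl <- function(values, groups, levels) {
  out <- lapply(levels, function(g) {
    ci <- t_ci(values[groups == g])
    tibble::tibble(group = g, n = ci$n, mean = ci$mean, se = ci$se,
                   ci_lo = ci$lo, ci_hi = ci$hi)
  })
  dplyr::bind_rows(out)
}

# compact letter display: maximal cliques of the "not significantly
# different" graph, ordered by group mean (groups are few, so subsets are
# enumerated exhaustively)
assign_letters <- function(pairwise_p, means, alpha = 0.05) {
  g <- names(means)
  if (length(g) == 1L) return(stats::setNames("a", g))
  nsd <- function(a, b) {
    p <- pairwise_p[[paste(sort(c(a, b)), collapse = "|")]]
    is.null(p) || is.na(p) || p >= alpha
  }
  subsets <- list()
  for (sz in length(g):1) {
    for (idx in utils::combn(length(g), sz, simplify = FALSE)) {
      s <- g[idx]
      pairs_ok <- all(apply(utils::combn(s, min(2, length(s))), 2,
                            function(pr) length(pr) < 2 || nsd(pr[1], pr[2])))
      if (length(s) == 1L) pairs_ok <- TRUE
      if (pairs_ok && !any(vapply(subsets, function(t) all(s %in% t), logical(1))))
        subsets <- c(subsets, list(s))
    }
  }
  # order cliques by the mean of their best group so letters read a, b, ...
  ord <- order(vapply(subsets, function(s) min(means[s]), numeric(1)))
  subsets <- subsets[ord]
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (i in seq_along(subsets)) {
    for (m in subsets[[i]]) letters_out[m] <- paste0(letters_out[m], letters[i])
  }
  letters_out
}

#' One-way ANOVA of seasonal residuals against smoke exposure
#'
#' Tests weekly spline residuals either between smoke and no-smoke weeks
#' (`grouping = "smoke_vs_no_smoke"`) or across density classes
#' (`grouping = "by_density"`: none/low/medium/high). If the ANOVA is
#' significant at `alpha`, all pairwise Student's t tests (pooled two-sample
#' variance, no multiplicity correction beyond the ANOVA gate) are computed
#' and significance letters assigned; groups sharing no letter differ at
#' `p < alpha`.
#'
#' By default observations are weekly residuals pooled across lakes;
#' `per_lake_mean = TRUE` is a sensitivity mode that first averages
#' residuals per lake and group.
#'
#' @param data Residual rows (needs `residual`, `label`, and `density` for
#'   the by-density grouping; `lake_id` for the per-lake mode).
#' @param grouping `"smoke_vs_no_smoke"` or `"by_density"`.
#' @param value Column tested (default `"residual"`).
#' @param per_lake_mean Average within lake and group first (default FALSE).
#' @param alpha Significance level gating the post hoc tests (default 0.05).
#' @return A list of class `"residual_anova"`: `anova` (tibble with
#'   `F`, `df_between`, `df_within`, `p`), `pairwise` (tibble `group_a`,
#'   `group_b`, `p`; zero rows when the gate fails), and `groups` (tibble
#'   `group`, `n`, `mean`, `se`, `ci_lo`, `ci_hi`, `letter`).
#' @export
residual_anova <- function(data,
                           grouping = c("smoke_vs_no_smoke", "by_density"),
                           value = "residual", per_lake_mean = FALSE,
                           alpha = 0.05) {
  grouping <- match.arg(grouping)
  y <- data[[value]]
  grp <- if (grouping == "smoke_vs_no_smoke") data$label else data$density
  lvls <- if (grouping == "smoke_vs_no_smoke") c("no_smoke", "smoke") else
    c("none", "low", "medium", "high")
  keep <- !is.na(y) & !is.na(grp)
  y <- y[keep]; grp <- grp[keep]
  if (per_lake_mean) {
    d <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(lake_id = data$lake_id[keep], y = y, grp = grp),
                      .data$lake_id, .data$grp),
      y = mean(.data$y), .groups = "drop")
    y <- d$y; grp <- d$grp
  }
  lvls <- lvls[lvls %in% grp]
  counts <- table(factor(grp, levels = lvls))
  if (length(lvls) < 2L)
    abort_contract("ANOVA needs at least two groups with observations")
  if (any(counts < 2L))
    abort_contract(sprintf("degenerate group with fewer than 2 observations: %s",
                           paste(names(counts)[counts < 2L], collapse = ", ")))
  f <- factor(grp, levels = lvls)
  # identical groups trigger R's "essentially perfect fit" warning; that
  # degenerate case is handled explicitly below (F = 0)
  av <- withCallingHandlers(
    stats::anova(stats::lm(y ~ f)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  result <- tibble::tibble(F = av$`F value`[1], df_between = av$Df[1],
                           df_within = av$Df[2], p = av$`Pr(>F)`[1])
  if (is.nan(result$F)) {  # 0/0: zero variance both between and within groups
    result$F <- 0
    result$p <- 1
  }

  pairwise <- tibble::tibble(group_a = character(), group_b = character(),
                             p = numeric())
  pw_map <- list()
  if (is.finite(result$p) && result$p < alpha) {
    for (pr in utils::combn(lvls, 2, simplify = FALSE)) {
      tt <- stats::t.test(y[grp == pr[1]], y[grp == pr[2]], var.equal = TRUE)
      pairwise <- dplyr::bind_rows(pairwise,
        tibble::tibble(group_a = pr[1], group_b = pr[2], p = tt$p.value))
      pw_map[[paste(sort(pr), collapse = "|")]] <- tt$p.value
    }
  }
  groups <- group_summary_tbl(y, grp, lvls)
  means <- stats::setNames(groups$mean, groups$group)
  groups$letter <- if (nrow(pairwise)) unname(assign_letters(pw_map, means, alpha)) else
    rep("a", nrow(groups))
  structure(list(anova = result, pairwise = pairwise, groups = groups,
                 grouping = grouping), class = "residual_anova")
}

#' @export
print.residual_anova <- function(x, ...) {
  cat(sprintf("<residual_anova> %s: F(%d, %d) = %.3f, p = %.3g\n",
              x$grouping, x$anova$df_between, x$anova$df_within,
              x$anova$F, x$anova$p))
  print(x$groups)
  invisible(x)
}

#' Meteorological season of a week
#'
#' Spring = March-May, summer = June-August, fall = September-November;
#' winter weeks return NA and are excluded from seasonal analyses.
#'
#' @param week_start Date vector (first day of each weekly bin).
#' @return Character vector over `c("spring","summer","fall")` with NAs.
#' @export
assign_season <- function(week_start) {
  m <- as.integer(format(as.Date(week_start), "%m"))
  out <- rep(NA_character_, length(m))
  out[m %in% 3:5] <- "spring"
  out[m %in% 6:8] <- "summer"
  out[m %in% 9:11] <- "fall"
  out
}

#' Seasonal smoke / no-smoke bloom-magnitude difference CIs
#'
#' For each lake and season with at least one smoke and one no-smoke week of
#' observed chlorophyll-a, computes the difference of the mean observed
#' chlorophyll-a (bloom magnitude) between smoke and no-smoke weeks; then,
#' per season, the mean of those per-lake differences across lakes with a
#' t-based 95% confidence interval.
#'
#' @param records Lake-week records (needs `lake_id`, `week_start`, `chla`,
#'   `label`).
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `season`, `n_lakes`, `mean_diff`, `ci_lo`, `ci_hi`.
#'   Seasons with fewer than 2 contributing lakes get NA CIs with a warning.
#' @export
seasonal_smoke_difference_ci <- function(records, conf = 0.95) {
  records$season <- assign_season(records$week_start)
  d <- records[!is.na(records$season) & !is.na(records$chla) &
                 !is.na(records$label), ]
  diffs <- d |>
    dplyr::group_by(.data$lake_id, .data$season) |>
    dplyr::summarise(
      n_smoke = sum(.data$label == "smoke"),
      n_clear = sum(.data$label == "no_smoke"),
      diff = mean(.data$chla[.data$label == "smoke"]) -
             mean(.data$chla[.data$label == "no_smoke"]),
      .groups = "drop") |>
    dplyr::filter(.data$n_smoke >= 1L, .data$n_clear >= 1L)
  out <- lapply(c("spring", "summer", "fall"), function(s) {
    ci <- t_ci(diffs$diff[diffs$season == s], conf)
    if (ci$n > 0 && ci$n < 2)
      warn(sprintf("season %s has %d contributing lake(s); CI is NA", s, ci$n))
    tibble::tibble(season = s, n_lakes = ci$n, mean_diff = ci$mean,
                   ci_lo = ci$lo, ci_hi = ci$hi)
  })
  dplyr::bind_rows(out)
}

#' Event-aligned chlorophyll-a composite
#'
#' Summarizes chlorophyll-a by week relative to smoke events (relative week
#' 0 = event week). With filtering on, lakes whose fraction of observed
#' weeks at the method detection limit over their full series exceeds
#' `mdl_filter` are excluded before summarizing.
#'
#' @param windows Event windows from [extract_all_event_windows()].
#' @param records Full lake-week records (used for the per-lake at-MDL
#'   fraction).
#' @param mdl_filter At-MDL fraction above which a lake is dropped
#'   (default 0.8).
#' @param apply_filter Apply the at-MDL lake filter (default TRUE).
#' @return Tibble: `relative_week`, `n`, `mean`, `median`.
#' @export
event_aligned_summary <- function(windows, records, mdl_filter = 0.8,
                                  apply_filter = TRUE) {
  if (nrow(windows) == 0L)
    return(tibble::tibble(relative_week = integer(), n = integer(),
                          mean = numeric(), median = numeric()))
  if (apply_filter) {
    frac <- records[!is.na(records$chla), ] |>
      dplyr::group_by(.data$lake_id) |>
      dplyr::summarise(frac = mean(.data$at_mdl), .groups = "drop")
    drop <- frac$lake_id[!is.na(frac$frac) & frac$frac > mdl_filter]
    windows <- windows[!windows$lake_id %in% drop, ]
  }
  windows |>
    dplyr::filter(!is.na(.data$chla)) |>
    dplyr::group_by(relative_week = .data$relative_week) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$chla),
                     median = median(.data$chla), .groups = "drop") |>
    dplyr::arrange(.data$relative_week)
}

delta_bin_labels <- function(edges) {
  n <- length(edges) - 1L
  lab <- character(n)
  for (i in seq_len(n)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    lab[i] <- if (is.infinite(lo)) sprintf("<= %g", hi)
      else if (is.infinite(hi)) sprintf("> %g", lo)
      else sprintf("(%g, %g]", lo, hi)
  }
  lab
}

#' Per-lake smoke response delta with map binning
#'
#' For each smoke-impacted lake with at least one smoke-week and one
#' no-smoke-week residual, the delta is the mean residual over smoke weeks
#' minus the mean residual over no-smoke weeks (ug/L), binned on the
#' configured right-closed map edges.
#'
#' @param residuals Residual rows (needs `lake_id`, `label`, and the value
#'   column).
#' @param classes Optional [classify_lakes()] output restricting the
#'   computation to smoke-impacted lakes.
#' @param strata A [strata_config()] supplying the bin edges.
#' @param value Residual column the deltas are computed from (default
#'   `"residual"`).
#' @return Tibble: `lake_id`, `delta`, `bin` (factor over all bin labels).
#'   Lakes skipped for missing a label class are reported in the
#'   `"skipped"` attribute (`lake_id`, `reason`).
#' @export
per_lake_smoke_delta <- function(residuals, classes = NULL,
                                 strata = strata_config(),
                                 value = "residual") {
  if (!is.null(classes)) {
    keep <- classes$lake_id[classes$impact_class == "smoke_impacted"]
    residuals <- residuals[residuals$lake_id %in% keep, ]
  }
  residuals$residual <- residuals[[value]]
  per <- residuals |>
    dplyr::filter(!is.na(.data$residual), !is.na(.data$label)) |>
    dplyr::group_by(.data$lake_id) |>
    dplyr::summarise(
      n_smoke = sum(.data$label == "smoke"),
      n_clear = sum(.data$label == "no_smoke"),
      delta = mean(.data$residual[.data$label == "smoke"]) -
              mean(.data$residual[.data$label == "no_smoke"]),
      .groups = "drop")
  skipped <- per[per$n_smoke == 0L | per$n_clear == 0L, ]
  skipped <- tibble::tibble(
    lake_id = skipped$lake_id,
    reason = ifelse(skipped$n_smoke == 0L, "no smoke-week residuals",
                    "no no-smoke-week residuals"))
  per <- per[per$n_smoke >= 1L & per$n_clear >= 1L, ]
  edges <- strata$delta_bin_edges
  out <- tibble::tibble(
    lake_id = per$lake_id, delta = per$delta,
    bin = cut(per$delta, breaks = edges, labels = delta_bin_labels(edges),
              right = TRUE, include.lowest = TRUE))
  attr(out, "skipped") <- skipped
  out
}

#' Classify lake trophic status from baseline chlorophyll-a
#'
#' Baseline is conventionally the lake's mean observed chlorophyll-a over
#' its no-smoke weeks, so the stratifier is not contaminated by the smoke
#' response. Boundaries 2 and 7 ug/L belong to mesotrophic.
#'
#' @param baseline Baseline chlorophyll-a (ug/L; NA gives NA).
#' @param breaks Thresholds from [strata_config()].
#' @return Character vector over
#'   `c("oligotrophic","mesotrophic","eutrophic")`.
#' @export
classify_trophic <- function(baseline, breaks = c(2, 7)) {
  out <- rep(NA_character_, length(baseline))
  out[!is.na(baseline) & baseline < breaks[1]] <- "oligotrophic"
  out[!is.na(baseline) & baseline >= breaks[1] & baseline <= breaks[2]] <- "mesotrophic"
  out[!is.na(baseline) & baseline > breaks[2]] <- "eutrophic"
  out
}

#' Classify lake elevation
#'
#' Boundaries (default 255 and 538 m, the lowest / middle-two / highest
#' quartiles of the smoke-impacted 2018 CONUS lake population) belong to the
#' medium class.
#'
#' @param elevation Elevation (m; NA gives NA).
#' @param breaks Thresholds from [strata_config()] or [elevation_bounds()].
#' @return Character vector over `c("lower","medium","higher")`.
#' @export
classify_elevation <- function(elevation, breaks = c(255, 538)) {
  out <- rep(NA_character_, length(elevation))
  out[!is.na(elevation) & elevation < breaks[1]] <- "lower"
  out[!is.na(elevation) & elevation >= breaks[1] & elevation <= breaks[2]] <- "medium"
  out[!is.na(elevation) & elevation > breaks[2]] <- "higher"
  out
}

#' Elevation class bounds from population quartiles
#'
#' @param elevation Elevations (m) of the lake population being stratified.
#' @return Numeric length-2 vector: the 25% and 75% quantiles.
#' @export
elevation_bounds <- function(elevation) {
  unname(quantile(elevation, c(0.25, 0.75), na.rm = TRUE))
}

#' Stratified summary of per-lake response values
#'
#' Mean and t-based 95% CI of a per-lake value (typically the smoke response
#' delta) within each stratum of a classification. Strata with no lakes
#' report `n = 0` and NA; strata with a single lake report an NA CI with a
#' warning.
#'
#' @param lake_values Tibble with one row per lake: a `value` column and a
#'   class column.
#' @param class_col Name of the class column.
#' @param value_col Name of the value column (default `"delta"`).
#' @param levels Stratum levels (default: sorted unique classes).
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `stratum`, `n`, `mean`, `se`, `ci_lo`, `ci_hi`.
#' @export
stratified_residual_summary <- function(lake_values, class_col,
                                        value_col = "delta", levels = NULL,
                                        conf = 0.95) {
  cls <- lake_values[[class_col]]
  val <- lake_values[[value_col]]
  levels <- levels %||% sort(unique(cls[!is.na(cls)]))
  out <- lapply(levels, function(g) {
    ci <- t_ci(val[!is.na(cls) & cls == g], conf)
    if (ci$n == 1L)
      warn(sprintf("stratum %s has a single lake; CI is NA", g))
    tibble::tibble(stratum = g, n = ci$n, mean = ci$mean, se = ci$se,
                   ci_lo = ci$lo, ci_hi = ci$hi)
  })
  dplyr::bind_rows(out)
}
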