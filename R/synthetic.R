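#' Configuration for the synthetic lake landscape generator
#'
#' Defines the study conditions emulated by the generator: a population of
#' lakes with Gaussian-bump seasonal chlorophyll-a phenology, multiplicative
#' lognormal observation noise, left-censoring at a method detection limit
#' (MDL), an independent weekly smoke schedule with three density classes,
#' and an ephemeral additive chlorophyll-a response to smoke that persists
#' for `persistence_weeks` weeks after each smoke week.
#'
#' Defaults describe a 2018-like CONUS season: a 52-week year, peak blooms
#' between late spring and early fall, ~5 smoke weeks per lake-year, and
#' density-keyed responses of 0.3/1.6/1.2 ug/L for low/medium/high smoke.
#'
#' @param n_lakes Number of lakes.
#' @param n_weeks Number of weekly bins (>= 8).
#' @param seed Integer seed; every random draw of the generator derives from
#'   it, so identical configs reproduce identical landscapes.
#' @param mdl Method detection limit (ug/L, > 0). Values below it are
#'   reported at the MDL with `at_mdl = TRUE` (left-censoring).
#' @param seasonal_peak_range Range (ug/L) of per-lake peak bloom amplitude.
#' @param peak_week_range Range (weeks) of per-lake peak timing.
#' @param peak_width_range Range (weeks) of per-lake Gaussian bump SD.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise (>= 0); the lognormal is parameterized to have mean 1 and exactly
#'   this CV.
#' @param smoke_week_prob Probability that any given week is a smoke week.
#' @param density_probs Named probabilities over `c("low","medium","high")`
#'   for the density class of a smoke week; must sum to 1.
#' @param effect_by_density Named additive chlorophyll-a uplift (ug/L >= 0)
#'   injected during a smoke week of each density class.
#' @param persistence_weeks Number of weeks the uplift persists after the
#'   smoke week itself (0 = event week only).
#' @param elevation_range Range (m) of lake elevations (uniform).
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_lakescape()]
#' @export
sim_config <- function(n_lakes = 100L,
                       n_weeks = 52L,
                       seed = 1L,
                       mdl = 0.1,
                       seasonal_peak_range = c(1, 20),
                       peak_week_range = c(20, 36),
                       peak_width_range = c(4, 10),
                       noise_cv = 0.3,
                       smoke_week_prob = 0.1,
                       density_probs = c(low = 0.5, medium = 0.3, high = 0.2),
                       effect_by_density = c(low = 0.3, medium = 1.6, high = 1.2),
                       persistence_weeks = 1L,
                       elevation_range = c(0, 1500)) {
  if (!is_count(n_lakes)) abort_config("n_lakes", "must be a non-negative integer")
  if (!is_count(n_weeks, min = 8L)) abort_config("n_weeks", "must be an integer >= 8")
  if (!is_count(abs(seed))) abort_config("seed", "must be an integer")
  if (!is.numeric(mdl) || length(mdl) != 1L || !is.finite(mdl) || mdl <= 0)
    abort_config("mdl", "must be a single concentration > 0")
  if (!is_range(seasonal_peak_range) || seasonal_peak_range[1] <= 0)
    abort_config("seasonal_peak_range", "must be an increasing positive range")
  if (!is_range(peak_week_range)) abort_config("peak_week_range", "must be a range")
  if (!is_range(peak_width_range) || peak_width_range[1] <= 0)
    abort_config("peak_width_range", "must be an increasing positive range")
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || !is.finite(noise_cv) || noise_cv < 0)
    abort_config("noise_cv", "must be >= 0")
  if (!is_prob(smoke_week_prob)) abort_config("smoke_week_prob", "must be a probability in [0,1]")
  if (!is.numeric(density_probs) || !setequal(names(density_probs), c("low", "medium", "high")) ||
      any(density_probs < 0) || any(density_probs > 1) ||
      abs(sum(density_probs) - 1) > 1e-9)
    abort_config("density_probs", "must be probabilities named low/medium/high summing to 1")
  if (!is.numeric(effect_by_density) ||
      !setequal(names(effect_by_density), c("low", "medium", "high")) ||
      any(!is.finite(effect_by_density)) || any(effect_by_density < 0))
    abort_config("effect_by_density", "must be non-negative uplifts named low/medium/high")
  if (!is_count(persistence_weeks)) abort_config("persistence_weeks", "must be an integer >= 0")
  if (!is_range(elevation_range)) abort_config("elevation_range", "must be a range")

  structure(
    list(n_lakes = as.integer(n_lakes), n_weeks = as.integer(n_weeks),
         seed = as.integer(seed), mdl = mdl,
         seasonal_peak_range = seasonal_peak_range,
         peak_week_range = peak_week_range,
         peak_width_range = peak_width_range,
         noise_cv = noise_cv, smoke_week_prob = smoke_week_prob,
         density_probs = density_probs[c("low", "medium", "high")],
         effect_by_density = effect_by_density[c("low", "medium", "high")],
         persistence_weeks = as.integer(persistence_weeks),
         elevation_range = elevation_range),
    class = "sim_config")
}

assert_sim_config <- function(config) {
  if (!inherits(config, "sim_config"))
    abort_config("config", "must be created with sim_config()")
  config
}

#' Generate a synthetic lake population
#'
#' Draws `n_lakes` lakes with coordinates in a CONUS-like box, uniform
#' elevations over `elevation_range`, lognormal surface areas, and per-lake
#' seasonal curve parameters (peak amplitude, peak week, bump width) drawn
#' uniformly from the configured ranges.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per lake: `lake_id`, `lat`, `lon`,
#'   `elevation`, `area`, `peak_chla`, `peak_week`, `peak_width`.
#' @export
generate_lake_population <- function(config) {
  assert_sim_config(config)
  n <- config$n_lakes
  if (n == 0L) {
    return(tibble::tibble(lake_id = character(), lat = numeric(),
                          lon = numeric(), elevation = numeric(),
                          area = numeric(), peak_chla = numeric(),
                          peak_week = numeric(), peak_width = numeric()))
  }
  withr::with_seed(derive_seed(config$seed, 1L), {
    tibble::tibble(
      lake_id   = sprintf("L%05d", seq_len(n)),
      lat       = runif(n, 25, 49),
      lon       = runif(n, -125, -67),
      elevation = runif(n, config$elevation_range[1], config$elevation_range[2]),
      area      = exp(runif(n, log(0.75), log(50))),
      peak_chla = runif(n, config$seasonal_peak_range[1], config$seasonal_peak_range[2]),
      peak_week = runif(n, config$peak_week_range[1], config$peak_week_range[2]),
      peak_width = runif(n, config$peak_width_range[1], config$peak_width_range[2])
    )
  })
}

# deterministic seasonal curve of one lake, ug/L at integer weeks
seasonal_curve <- function(lake, n_weeks) {
  w <- seq_len(n_weeks)
  lake$peak_chla * exp(-0.5 * ((w - lake$peak_week) / lake$peak_width)^2)
}

censor_series <- function(latent, mdl) {
  at_mdl <- latent < mdl
  tibble::tibble(chla = ifelse(at_mdl, mdl, latent), at_mdl = at_mdl,
                 latent = latent)
}

#' Simulate one lake's weekly chlorophyll-a series
#'
#' The latent series is the lake's Gaussian seasonal bump multiplied by
#' lognormal noise with mean 1 and CV `config$noise_cv`; values below the
#' MDL are reported at the MDL with `at_mdl = TRUE`.
#'
#' @param lake One row of [generate_lake_population()] (list or tibble row).
#' @param config A [sim_config()].
#' @param seed Integer seed for this series.
#' @return A tibble: `week_index`, `chla` (censored, ug/L), `at_mdl`,
#'   `latent` (pre-censoring value, kept so injected ground truth can be
#'   verified exactly).
#' @export
simulate_chla_series <- function(lake, config, seed) {
  assert_sim_config(config)
  curve <- seasonal_curve(lake, config$n_weeks)
  cv <- config$noise_cv
  noise <- if (cv == 0) rep(1, config$n_weeks) else {
    sdlog <- sqrt(log(1 + cv^2))
    withr::with_seed(seed, rlnorm(config$n_weeks, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  out <- censor_series(curve * noise, config$mdl)
  tibble::tibble(week_index = seq_len(config$n_weeks), out)
}

#' Simulate a weekly smoke schedule
#'
#' Each week is independently a smoke week with probability
#' `smoke_week_prob`; smoke weeks draw a density class from `density_probs`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Character vector of length `n_weeks` over
#'   `c("none","low","medium","high")`.
#' @export
simulate_smoke_schedule <- function(config, seed) {
  assert_sim_config(config)
  withr::with_seed(seed, {
    smoke <- runif(config$n_weeks) < config$smoke_week_prob
    dens <- rep("none", config$n_weeks)
    if (any(smoke)) {
      dens[smoke] <- sample(names(config$density_probs), sum(smoke),
                            replace = TRUE, prob = config$density_probs)
    }
    dens
  })
}

#' Inject the smoke response into a chlorophyll-a series
#'
#' For every smoke week `w` of density `d`, adds `effect_by_density[d]` ug/L
#' to weeks `w .. w + persistence_weeks` (truncated at the series end;
#' overlapping events sum). The addition acts on the latent (pre-censoring)
#' series and censoring at the MDL is re-applied afterwards.
#'
#' @param series A tibble from [simulate_chla_series()] (needs `latent`).
#' @param schedule Character vector from [simulate_smoke_schedule()], same
#'   length as the series.
#' @param config A [sim_config()].
#' @return A list: `series` (modified, same columns), `truth` a tibble
#'   (`week_index`, `uplift`) with the exact added ug/L per week, and
#'   `event_weeks`, the indices of the smoke weeks.
#' @export
inject_smoke_response <- function(series, schedule, config) {
  assert_sim_config(config)
  n <- nrow(series)
  if (length(schedule) != n)
    abort_validation(sprintf(
      "series (%d weeks) and schedule (%d weeks) differ in length", n, length(schedule)))
  uplift <- numeric(n)
  events <- which(schedule %in% names(config$effect_by_density))
  for (w in events) {
    span <- w:min(n, w + config$persistence_weeks)
    uplift[span] <- uplift[span] + config$effect_by_density[[schedule[w]]]
  }
  out <- censor_series(series$latent + uplift, config$mdl)
  list(series = tibble::tibble(week_index = series$week_index, out),
       truth = tibble::tibble(week_index = series$week_index, uplift = uplift),
       event_weeks = events)
}

#' Simulate a full lake landscape with known ground truth
#'
#' Runs the generator end to end: lake population, per-lake chlorophyll-a
#' series, per-lake smoke schedules, and injected smoke responses. The
#' output tables use the same CSV dialects the ingest readers accept, so a
#' simulated landscape exercises the whole pipeline.
#'
#' @param config A [sim_config()].
#' @param origin First day of week 1 in the emitted `week_start` dates.
#' @return A list of class `"lakescape"`: `chla` (lake_id, week_start, chla,
#'   n_pixels, at_mdl), `smoke` (lake_id, week_start, density), `meta`
#'   (lake_id, lat, lon, elevation, area), `truth` (lake_id, week_index,
#'   uplift, density, latent), and `config`.
#' @export
simulate_lakescape <- function(config, origin = as.Date("2018-01-01")) {
  assert_sim_config(config)
  pop <- generate_lake_population(config)
  nw <- config$n_weeks
  weeks <- week_start(seq_len(nw), origin)
  n_pixels <- withr::with_seed(derive_seed(config$seed, 2L),
                               sample(3:60, max(config$n_lakes, 1L), replace = TRUE))
  # per-lake stream seeds drawn from one master stream: arithmetically
  # related set.seed() values can yield correlated generator streams, which
  # would couple each lake's noise to its smoke schedule
  stream_seeds <- withr::with_seed(derive_seed(config$seed, 3L),
                                   sample.int(2147483646L,
                                              max(2L * config$n_lakes, 1L)))
  # column accumulators (lake-major), avoiding per-lake tibble construction
  chla_v <- latent_v <- uplift_v <- numeric(nw * config$n_lakes)
  atmdl_v <- logical(nw * config$n_lakes)
  sched_v <- character(nw * config$n_lakes)
  cv <- config$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  for (i in seq_len(config$n_lakes)) {
    lake <- pop[i, ]
    curve <- seasonal_curve(lake, nw)
    noise <- if (cv == 0) rep(1, nw) else
      withr::with_seed(stream_seeds[2L * i - 1L],
                       rlnorm(nw, meanlog = -sdlog^2 / 2, sdlog = sdlog))
    sched <- simulate_smoke_schedule(config, stream_seeds[2L * i])
    uplift <- numeric(nw)
    for (w in which(sched != "none")) {
      span <- w:min(nw, w + config$persistence_weeks)
      uplift[span] <- uplift[span] + config$effect_by_density[[sched[w]]]
    }
    latent <- curve * noise + uplift
    at <- latent < config$mdl
    idx <- (i - 1L) * nw + seq_len(nw)
    chla_v[idx] <- ifelse(at, config$mdl, latent)
    latent_v[idx] <- latent
    uplift_v[idx] <- uplift
    atmdl_v[idx] <- at
    sched_v[idx] <- sched
  }
  ids <- rep(pop$lake_id, each = nw)
  weeks_all <- rep(weeks, times = config$n_lakes)
  structure(list(
    chla = tibble::tibble(lake_id = ids, week_start = weeks_all,
                          chla = chla_v, n_pixels = rep(n_pixels[seq_len(config$n_lakes)], each = nw),
                          at_mdl = atmdl_v),
    smoke = tibble::tibble(lake_id = ids, week_start = weeks_all,
                           density = sched_v),
    meta = pop[, c("lake_id", "lat", "lon", "elevation", "area")],
    truth = tibble::tibble(lake_id = ids,
                           week_index = rep(seq_len(nw), times = config$n_lakes),
                           uplift = uplift_v, density = sched_v,
                           latent = latent_v),
    config = config
  ), class = "lakescape")
}

#' Write a simulated landscape to CSV files
#'
#' Emits `chla.csv`, `smoke_weekly.csv`, `lake_meta.csv` and `truth.csv`
#' (the last is ground truth, not a pipeline input) in the dialects the
#' ingest readers expect.
#'
#' @param x A `"lakescape"` from [simulate_lakescape()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named paths written.
#' @export
write_lakescape <- function(x, dir) {
  stopifnot(inherits(x, "lakescape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(chla = file.path(dir, "chla.csv"),
             smoke = file.path(dir, "smoke_weekly.csv"),
             meta = file.path(dir, "lake_meta.csv"),
             truth = file.path(dir, "truth.csv"))
  readr::write_csv(x$chla, paths[["chla"]])
  readr::write_csv(x$smoke, paths[["smoke"]])
  readr::write_csv(x$meta, paths[["meta"]])
  readr::write_csv(x$truth, paths[["truth"]])
  invisible(paths)
}
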