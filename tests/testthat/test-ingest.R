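test_that("cyanobacteria index conversion follows the power law", {
  expect_equal(ci_to_chla(0, conversion_params(scale = 2, exponent = 1, offset = 0)), 0)
  expect_equal(ci_to_chla(3, conversion_params(scale = 2, exponent = 1, offset = 0)), 6)
  expect_error(ci_to_chla(-0.1), class = "lakesmoke_validation_error")

  # randomized grid vs direct evaluation, plus monotonicity and roundtrip
  set.seed(1)
  for (i in 1:20) {
    p <- conversion_params(scale = runif(1, 0.1, 100),
                           exponent = runif(1, 0.2, 3),
                           offset = runif(1, 0, 5))
    ci <- sort(runif(25, 0, 10))
    got <- ci_to_chla(ci, p)
    expect_equal(got, p$offset + p$scale * ci^p$exponent)
    expect_false(is.unsorted(got))
    back <- ((got - p$offset) / p$scale)^(1 / p$exponent)
    expect_equal(back, ci, tolerance = 1e-9)
  }
})

test_that("area-normalized lake mean is sum over resolved pixels", {
  expect_equal(area_mean_chla(c(4, 6)), 5)
  expect_true(is.na(area_mean_chla(numeric())))
  expect_error(area_mean_chla(c(1, -2)), class = "lakesmoke_validation_error")
  set.seed(2)
  for (i in 1:20) {
    v <- runif(sample(1:40, 1), 0, 50)
    expect_equal(area_mean_chla(v), sum(v) / length(v))
  }
})

test_that("chlorophyll reader parses, validates, and converts ci", {
  tbl <- tibble::tibble(
    lake_id = "A", week_start = as.Date("2018-01-01") + c(0, 7, 14),
    chla = c(1, 2, 3), n_pixels = c(5L, 5L, 5L), at_mdl = FALSE)
  expect_equal(nrow(read_chla_weekly(write_temp_csv(tbl))), 3L)

  expect_error(read_chla_weekly(write_temp_csv(tbl[, -1])), "lake_id",
               class = "lakesmoke_format_error")

  bad <- tbl; bad$chla[1] <- -1
  expect_error(read_chla_weekly(write_temp_csv(bad)), "row\\(s\\) 1",
               class = "lakesmoke_validation_error")

  ci_tbl <- tbl; ci_tbl$ci <- c(0, 1, 2); ci_tbl$chla <- NULL
  got <- read_chla_weekly(write_temp_csv(ci_tbl),
                          conversion_params(scale = 3, exponent = 1, offset = 0))
  expect_equal(got$chla, c(0, 3, 6))

  # zero resolved pixels force NA chlorophyll, row retained
  napx <- tbl; napx$n_pixels[2] <- 0L
  got2 <- read_chla_weekly(write_temp_csv(napx))
  expect_true(is.na(got2$chla[2]) && nrow(got2) == 3L)
})

test_that("week bins are 7-day intervals from the origin", {
  expect_equal(week_start(1), as.Date("2018-01-01"))
  expect_equal(week_start(52), as.Date("2018-12-24"))
  expect_equal(week_index(as.Date("2018-01-07")), 1L)
  expect_equal(week_index(as.Date("2018-01-08")), 2L)
  expect_equal(week_index(as.Date("2018-12-30")), 52L)
  expect_equal(week_index(week_start(1:52)), 1:52)
})

test_that("lake-week join is a key-complete outer join with event labels", {
  chl <- tibble::tibble(
    lake_id = "A", week_start = week_start(1:3), chla = c(1, 2, 3),
    n_pixels = 5L, at_mdl = FALSE)
  smoke <- tibble::tibble(lake_id = "A", week_start = week_start(2),
                          density = "low")
  rec <- join_by_lake_week(chl, smoke)
  expect_equal(rec$label, c("no_smoke", "smoke", "no_smoke"))
  expect_equal(rec$density, c("none", "low", "none"))

  # empty smoke table: everything no_smoke
  rec0 <- join_by_lake_week(chl, smoke[0, ])
  expect_true(all(rec0$label == "no_smoke"))

  # explicit NA density is missing, not none
  smoke_na <- tibble::tibble(lake_id = "A", week_start = week_start(2),
                             density = NA_character_)
  recna <- join_by_lake_week(chl, smoke_na)
  expect_identical(recna$label, c("no_smoke", NA, "no_smoke"))

  # duplicates rejected
  expect_error(join_by_lake_week(chl[c(1, 1, 2), ], smoke),
               class = "lakesmoke_validation_error")

  # randomized tables: row count equals the union of key pairs
  set.seed(3)
  for (i in 1:10) {
    lakes <- sprintf("L%d", 1:4)
    c_keys <- unique(tibble::tibble(
      lake_id = sample(lakes, 20, TRUE), week_start = week_start(sample(1:8, 20, TRUE))))
    s_keys <- unique(tibble::tibble(
      lake_id = sample(lakes, 15, TRUE), week_start = week_start(sample(1:8, 15, TRUE))))
    chl_r <- dplyr::mutate(c_keys, chla = runif(dplyr::n()), n_pixels = 3L,
                           at_mdl = FALSE)
    smoke_r <- dplyr::mutate(s_keys, density = sample(c("none", "low", "high"),
                                                      dplyr::n(), TRUE))
    rec_r <- join_by_lake_week(chl_r, smoke_r)
    want <- length(union(paste(c_keys$lake_id, c_keys$week_start),
                         paste(s_keys$lake_id, s_keys$week_start)))
    expect_equal(nrow(rec_r), want)
    expect_false(anyDuplicated(paste(rec_r$lake_id, rec_r$week_start)) > 0)
  }
})

test_that("simulated landscapes round-trip through the CSV readers", {
  sim <- simulate_lakescape(test_config())
  dir <- withr::local_tempdir()
  paths <- write_lakescape(sim, dir)
  chl <- read_chla_weekly(paths[["chla"]])
  smoke <- read_smoke_weekly(paths[["smoke"]])
  meta <- read_lake_meta(paths[["meta"]])
  expect_equal(chl$chla, sim$chla$chla)
  expect_equal(smoke$density, sim$smoke$density)
  expect_equal(meta$elevation, sim$meta$elevation)
  # parse -> serialize is idempotent
  p2 <- write_temp_csv(chl)
  expect_identical(read_chla_weekly(p2), chl)
})
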