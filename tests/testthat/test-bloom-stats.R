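make_resid <- function(values, labels, lake = "A", density = NULL) {
  tibble::tibble(lake_id = lake, residual = values, std_residual = values,
                 label = labels,
                 density = density %||% ifelse(labels == "smoke", "low", "none"))
}

test_that("ANOVA matches the sum-of-squares oracle and handles degeneracy", {
  # identical groups: zero between-group variance
  d0 <- make_resid(c(1, 1, 1, 1), rep(c("no_smoke", "smoke"), each = 2))
  a0 <- residual_anova(d0)
  expect_equal(a0$anova$F, 0)

  d1 <- make_resid(c(0, 1, 2, 10, 11, 12),
                   rep(c("no_smoke", "smoke"), each = 3))
  a1 <- residual_anova(d1)
  o1 <- oracle_anova(d1$residual, d1$label)
  expect_equal(a1$anova$F, o1$F, tolerance = 1e-10)
  expect_equal(a1$anova$p, o1$p, tolerance = 1e-10)
  expect_equal(a1$anova$df_between, o1$df_between)
  expect_equal(a1$anova$df_within, o1$df_within)

  # random small instances, two to four groups
  set.seed(20)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    grp <- c("none", "low", "medium", "high")[1:k]
    n <- sample(3:12, k, replace = TRUE)
    d <- tibble::tibble(
      lake_id = "A", density = rep(grp, n),
      label = ifelse(rep(grp, n) == "none", "no_smoke", "smoke"),
      residual = rnorm(sum(n)))
    d$std_residual <- d$residual
    a <- residual_anova(d, "by_density")
    o <- oracle_anova(d$residual, d$density)
    expect_equal(a$anova$F, o$F, tolerance = 1e-8)
    expect_equal(a$anova$p, o$p, tolerance = 1e-8)
  }

  dd <- make_resid(c(1, 2, 3, 4), c("smoke", rep("no_smoke", 3)))
  expect_error(residual_anova(dd), "smoke", class = "lakesmoke_contract_error")
})

test_that("significance letters separate groups consistently with pairwise tests", {
  set.seed(31)
  d <- tibble::tibble(
    lake_id = "A",
    density = rep(c("none", "low", "medium"), each = 30),
    residual = c(rnorm(30, 0, .3), rnorm(30, 0, .3), rnorm(30, 5, .3)))
  d$label <- ifelse(d$density == "none", "no_smoke", "smoke")
  d$std_residual <- d$residual
  a <- residual_anova(d, "by_density")
  lt <- stats::setNames(a$groups$letter, a$groups$group)
  # none and low overlap; medium stands alone
  expect_true(any(strsplit(lt[["none"]], "")[[1]] %in% strsplit(lt[["low"]], "")[[1]]))
  expect_false(any(strsplit(lt[["medium"]], "")[[1]] %in%
                     strsplit(lt[["none"]], "")[[1]]))
  # letters agree with the pairwise decisions at alpha = 0.05
  for (r in seq_len(nrow(a$pairwise))) {
    shared <- any(strsplit(lt[[a$pairwise$group_a[r]]], "")[[1]] %in%
                    strsplit(lt[[a$pairwise$group_b[r]]], "")[[1]])
    expect_identical(shared, a$pairwise$p[r] >= 0.05)
  }
  # group summary CI uses the t quantile
  g <- a$groups[a$groups$group == "none", ]
  expect_equal(g$ci_hi - g$mean, qt(0.975, g$n - 1) * g$se, tolerance = 1e-12)
})

test_that("seasons are meteorological and seasonal CIs follow the t construction", {
  expect_equal(assign_season(as.Date(c("2018-03-05", "2018-06-11", "2018-09-03"))),
               c("spring", "summer", "fall"))
  expect_true(is.na(assign_season(as.Date("2018-01-15"))))

  # one lake, summer: smoke {5,5} vs no-smoke {3,3} -> diff 2; single lake -> NA CI
  rec <- tibble::tibble(
    lake_id = "A",
    week_start = as.Date("2018-07-02") + 7 * (0:3),
    chla = c(5, 5, 3, 3),
    label = c("smoke", "smoke", "no_smoke", "no_smoke"))
  expect_warning(ci <- seasonal_smoke_difference_ci(rec), "summer")
  expect_equal(ci$mean_diff[ci$season == "summer"], 2)
  expect_true(is.na(ci$ci_lo[ci$season == "summer"]))
  expect_equal(ci$n_lakes[ci$season == "spring"], 0L)

  # across many lakes the CI matches mean +/- t * se of the per-lake diffs
  set.seed(22)
  recs <- dplyr::bind_rows(lapply(1:12, function(i) tibble::tibble(
    lake_id = sprintf("L%02d", i),
    week_start = as.Date("2018-07-02") + 7 * (0:5),
    chla = rlnorm(6, 1, 0.4),
    label = sample(c("smoke", rep("no_smoke", 5))))))
  ci <- seasonal_smoke_difference_ci(recs)
  per <- sapply(split(recs, recs$lake_id), function(r)
    mean(r$chla[r$label == "smoke"]) - mean(r$chla[r$label == "no_smoke"]))
  want <- mean(per) + c(-1, 1) * qt(0.975, 11) * sd(per) / sqrt(12)
  s <- ci[ci$season == "summer", ]
  expect_equal(s$mean_diff, mean(per))
  expect_equal(c(s$ci_lo, s$ci_hi), want, tolerance = 1e-12)
})

test_that("event-aligned summaries filter at-MDL lakes and match a groupby oracle", {
  win <- function(lake, vals) tibble::tibble(
    lake_id = lake, anchor_week = 10L, relative_week = seq_along(vals) - 3L,
    week_index = 8L + seq_along(vals), chla = vals, at_mdl = FALSE,
    label = "smoke")
  recs <- tibble::tibble(
    lake_id = rep(c("A", "B"), each = 10),
    chla = 1, at_mdl = rep(c(TRUE, FALSE), c(9, 1))[c(1:10, 1:10)])
  # lake A: 90% at MDL -> excluded at the 0.8 filter
  recs$at_mdl <- c(rep(TRUE, 9), FALSE, rep(FALSE, 10))
  w <- dplyr::bind_rows(win("A", c(9, 9, 9, 9, 9)), win("B", c(1, 2, 3, 4, 5)))
  s <- event_aligned_summary(w, recs, mdl_filter = 0.8)
  expect_equal(s$mean, c(1, 2, 3, 4, 5))
  s_all <- event_aligned_summary(w, recs, apply_filter = FALSE)
  expect_equal(s_all$mean, c(5, 5.5, 6, 6.5, 7))
  expect_equal(s_all$n, rep(2L, 5))

  # constant chlorophyll: mean = median = constant
  wc <- dplyr::bind_rows(win("A", rep(4, 5)), win("B", rep(4, 5)))
  sc <- event_aligned_summary(wc, recs, apply_filter = FALSE)
  expect_true(all(sc$mean == 4) && all(sc$median == 4))

  # random windows vs direct recomputation
  set.seed(23)
  wr <- dplyr::bind_rows(lapply(1:6, function(i)
    win(sprintf("L%d", i), runif(5, 0, 10))))
  sr <- event_aligned_summary(wr, recs[0, ], apply_filter = FALSE)
  for (rw in unique(wr$relative_week)) {
    expect_equal(sr$mean[sr$relative_week == rw],
                 mean(wr$chla[wr$relative_week == rw]))
    expect_equal(sr$median[sr$relative_week == rw],
                 median(wr$chla[wr$relative_week == rw]))
  }

  expect_equal(nrow(event_aligned_summary(wr[0, ], recs)), 0L)
})

test_that("per-lake deltas and map bins follow the stated edges", {
  r <- make_resid(c(2, 4, 1, 1), c("smoke", "smoke", "no_smoke", "no_smoke"))
  d <- per_lake_smoke_delta(r)
  expect_equal(d$delta, 2)
  expect_equal(as.character(d$bin), "(1, 3]")

  # negating residuals negates the delta
  rn <- r; rn$residual <- -rn$residual
  expect_equal(per_lake_smoke_delta(rn)$delta, -2)

  # open top bin
  r12 <- make_resid(c(12, 0), c("smoke", "no_smoke"))
  expect_equal(as.character(per_lake_smoke_delta(r12)$bin), "> 10")

  # right-closed boundaries: delta exactly 1 belongs to (0, 1]
  r1 <- make_resid(c(1, 0), c("smoke", "no_smoke"))
  expect_equal(as.character(per_lake_smoke_delta(r1)$bin), "(0, 1]")

  # lakes without both label classes are skipped with a reason
  rna <- dplyr::bind_rows(
    make_resid(c(1, 2), c("smoke", "smoke"), lake = "S"),
    make_resid(c(1, 2), c("no_smoke", "no_smoke"), lake = "N"))
  dna <- per_lake_smoke_delta(rna)
  expect_equal(nrow(dna), 0L)
  expect_setequal(attr(dna, "skipped")$lake_id, c("S", "N"))

  # bin partition: every finite delta lands in exactly one bin
  set.seed(24)
  deltas <- tibble::tibble(
    lake_id = sprintf("L%d", 1:200),
    residual = 0, std_residual = 0)
  many <- dplyr::bind_rows(lapply(1:200, function(i)
    make_resid(c(runif(1, -30, 30), 0), c("smoke", "no_smoke"),
               lake = sprintf("L%d", i))))
  dm <- per_lake_smoke_delta(many)
  expect_equal(nrow(dm), 200L)
  expect_false(anyNA(dm$bin))
  expect_equal(sum(table(dm$bin)), 200L)
})

test_that("trophic and elevation classification respect closed middle boundaries", {
  expect_equal(classify_trophic(c(1.5, 2, 5, 7, 7.5)),
               c("oligotrophic", "mesotrophic", "mesotrophic", "mesotrophic",
                 "eutrophic"))
  expect_true(is.na(classify_trophic(NA_real_)))
  expect_equal(classify_elevation(c(100, 255, 400, 538, 600)),
               c("lower", "medium", "medium", "medium", "higher"))
  expect_true(is.na(classify_elevation(NA_real_)))
  # bounds recomputable as population quartiles
  set.seed(25)
  e <- runif(400, 0, 1500)
  expect_equal(elevation_bounds(e), unname(quantile(e, c(.25, .75))))
})

test_that("stratified summaries report every stratum with t-based CIs", {
  lv <- tibble::tibble(lake_id = c("A", "B"), delta = c(1, 3),
                       trophic = "eutrophic")
  s <- stratified_residual_summary(lv, "trophic",
                                   levels = c("oligotrophic", "mesotrophic",
                                              "eutrophic"))
  eu <- s[s$stratum == "eutrophic", ]
  expect_equal(eu$mean, 2)
  expect_equal(eu$ci_hi, 2 + qt(0.975, 1) * sd(c(1, 3)) / sqrt(2))
  empty <- s[s$stratum != "eutrophic", ]
  expect_true(all(empty$n == 0) && all(is.na(empty$mean)))

  expect_warning(
    stratified_residual_summary(lv[1, ], "trophic"), "single lake")
})

test_that("strata counts partition the classified lakes", {
  rr <- sim_records(test_config(n_lakes = 30))
  res <- suppressMessages(fit_lake_splines(rr$records))$residuals
  classes <- classify_lakes(rr$records)
  deltas <- per_lake_smoke_delta(res, classes)
  baseline <- res |>
    dplyr::filter(.data$label == "no_smoke", !is.na(.data$observed)) |>
    dplyr::group_by(.data$lake_id) |>
    dplyr::summarise(b = mean(.data$observed), .groups = "drop")
  tro <- classify_trophic(baseline$b)
  counts <- table(factor(tro, levels = c("oligotrophic", "mesotrophic",
                                         "eutrophic")))
  expect_equal(sum(counts), sum(!is.na(tro)))
  expect_equal(sum(!is.na(tro)), nrow(baseline))
})

test_that("density-ordered injected effects produce ordered group means", {
  cfg <- sim_config(n_lakes = 150, seed = 26, noise_cv = 0.3,
                    effect_by_density = c(low = 0.5, medium = 2, high = 4),
                    persistence_weeks = 0)
  rr <- sim_records(cfg)
  res <- suppressMessages(fit_lake_splines(rr$records))$residuals
  a <- residual_anova(res, "by_density", value = "std_residual")
  m <- stats::setNames(a$groups$mean, a$groups$group)
  expect_true(m[["none"]] < m[["low"]])
  expect_true(m[["low"]] < m[["medium"]])
  expect_true(m[["medium"]] < m[["high"]])
})
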