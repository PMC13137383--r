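test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_lakes = -1), "n_lakes",
               class = "lakesmoke_config_error")
  expect_error(sim_config(n_weeks = 4), "n_weeks",
               class = "lakesmoke_config_error")
  expect_error(sim_config(mdl = 0), "mdl", class = "lakesmoke_config_error")
  expect_error(sim_config(density_probs = c(low = 0.5, medium = 0.5, high = 0.5)),
               "density_probs", class = "lakesmoke_config_error")
  expect_error(sim_config(effect_by_density = c(low = -1, medium = 0, high = 0)),
               "effect_by_density", class = "lakesmoke_config_error")
})

test_that("lake population generation is seeded, sized, and uniform in elevation", {
  expect_equal(nrow(generate_lake_population(sim_config(n_lakes = 0))), 0L)

  cfg <- sim_config(n_lakes = 25, seed = 7)
  expect_identical(generate_lake_population(cfg), generate_lake_population(cfg))

  # uniform(0, 1000): mean 500, sd 1000/sqrt(12); check within 3 SEs
  cfg <- sim_config(n_lakes = 1000, seed = 11, elevation_range = c(0, 1000))
  pop <- generate_lake_population(cfg)
  se <- 1000 / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(pop$elevation) - 500), 3 * se)
  expect_true(all(pop$elevation >= 0 & pop$elevation <= 1000))
})

test_that("noiseless series equal the seasonal curve, clipped at the MDL", {
  cfg <- sim_config(n_lakes = 1, seed = 1, noise_cv = 0,
                    seasonal_peak_range = c(8, 8))
  lake <- generate_lake_population(cfg)[1, ]
  s <- simulate_chla_series(lake, cfg, seed = 5)
  curve <- lake$peak_chla * exp(-0.5 * ((s$week_index - lake$peak_week) / lake$peak_width)^2)
  expect_equal(s$chla, pmax(curve, cfg$mdl))
  expect_identical(s$at_mdl, curve < cfg$mdl)

  # amplitude entirely below the MDL: full censoring
  cfg2 <- sim_config(n_lakes = 1, seed = 1, noise_cv = 0, mdl = 0.5,
                     seasonal_peak_range = c(0.2, 0.3))
  lake2 <- generate_lake_population(cfg2)[1, ]
  s2 <- simulate_chla_series(lake2, cfg2, seed = 5)
  expect_true(all(s2$at_mdl))
  expect_true(all(s2$chla == 0.5))
})

test_that("lognormal noise reproduces the configured CV", {
  cfg <- sim_config(n_lakes = 1, seed = 1, noise_cv = 0.3, mdl = 1e-9,
                    seasonal_peak_range = c(10, 10),
                    peak_width_range = c(30, 30))
  lake <- generate_lake_population(cfg)[1, ]
  vals <- unlist(lapply(1:500, function(i) {
    s <- simulate_chla_series(lake, cfg, seed = i)
    s$chla[!s$at_mdl] / (lake$peak_chla *
      exp(-0.5 * ((s$week_index - lake$peak_week) / lake$peak_width)^2))
  }))
  cv <- sd(vals) / mean(vals)
  expect_lt(abs(cv - 0.3) / 0.3, 0.2)
})

test_that("smoke schedules honor probability and density settings", {
  cfg0 <- sim_config(smoke_week_prob = 0)
  expect_true(all(simulate_smoke_schedule(cfg0, 1) == "none"))

  cfg1 <- sim_config(smoke_week_prob = 1,
                     density_probs = c(low = 0, medium = 0, high = 1))
  expect_true(all(simulate_smoke_schedule(cfg1, 1) == "high"))

  # binomial check over 10,000 weeks
  cfg <- sim_config(n_weeks = 10000, smoke_week_prob = 0.2)
  sched <- simulate_smoke_schedule(cfg, 99)
  phat <- mean(sched != "none")
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(phat - 0.2), 3 * se)
  expect_identical(simulate_smoke_schedule(cfg, 99), sched)
})

test_that("smoke response injection matches its definition and ground truth", {
  cfg <- sim_config(n_lakes = 1, seed = 2, noise_cv = 0.4, mdl = 1e-12,
                    persistence_weeks = 1,
                    effect_by_density = c(low = 5, medium = 5, high = 5))
  lake <- generate_lake_population(cfg)[1, ]
  base <- simulate_chla_series(lake, cfg, seed = 9)

  # null effect leaves the series untouched
  cfg0 <- sim_config(n_lakes = 1, seed = 2, noise_cv = 0.4, mdl = 1e-12,
                     effect_by_density = c(low = 0, medium = 0, high = 0))
  sched <- simulate_smoke_schedule(cfg, seed = 4)
  inj0 <- inject_smoke_response(base, sched, cfg0)
  expect_equal(inj0$series$chla, base$chla)
  expect_true(all(inj0$truth$uplift == 0))

  # single smoke week, persistence 1, effect 5: uplift at w and w+1 only
  sched1 <- rep("none", cfg$n_weeks); sched1[20] <- "medium"
  inj1 <- inject_smoke_response(base, sched1, cfg)
  expect_equal(inj1$truth$uplift, c(rep(0, 19), 5, 5, rep(0, cfg$n_weeks - 21)))
  expect_equal(inj1$event_weeks, 20L)

  # conservation: uplift equals modified - original (mdl ~ 0, no censoring)
  schedr <- simulate_smoke_schedule(cfg, seed = 4)
  injr <- inject_smoke_response(base, schedr, cfg)
  expect_equal(injr$series$latent - base$latent, injr$truth$uplift)
  uncens <- !injr$series$at_mdl & !base$at_mdl
  expect_equal((injr$series$chla - base$chla)[uncens], injr$truth$uplift[uncens])

  expect_error(inject_smoke_response(base, sched1[-1], cfg),
               class = "lakesmoke_validation_error")
})

test_that("landscapes are deterministic given the seed and never emit sub-MDL values", {
  cfg <- sim_config(n_lakes = 8, seed = 21)
  a <- simulate_lakescape(cfg)
  b <- simulate_lakescape(cfg)
  expect_identical(a$chla, b$chla)
  expect_identical(a$smoke, b$smoke)
  expect_true(all(a$chla$chla >= cfg$mdl))
  expect_identical(a$chla$at_mdl, a$truth$latent < cfg$mdl)
})
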