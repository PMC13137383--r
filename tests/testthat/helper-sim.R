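# build analysis-ready lake-week records straight from a simulated
# landscape (the CSV round trip is covered by the pipeline tests)
sim_records <- function(config) {
  sim <- simulate_lakescape(config)
  list(sim = sim,
       records = join_by_lake_week(sim$chla, sim$smoke, sim$meta))
}

# a small, quiet default configuration for unit tests
test_config <- function(...) {
  args <- list(n_lakes = 10L, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}
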