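test_that("degenerate forcing produces a constant series", {
  cfg <- flat_config()
  air <- generate_air_series(cfg)
  expect_true(all(air$temp_c == 20))
  expect_equal(nrow(air), 7 * 24)
})

test_that("the same config and seed reproduce the series exactly", {
  cfg <- tiny_config(seed = 11L)
  expect_identical(generate_air_series(cfg), generate_air_series(cfg))
  sc1 <- simulate_scenario(cfg)
  sc2 <- simulate_scenario(cfg)
  expect_identical(sc1$records, sc2$records)
  expect_identical(sc1$truth, sc2$truth)
  cfg2 <- tiny_config(seed = 12L)
  expect_false(identical(generate_air_series(cfg2)$temp_c,
                         generate_air_series(cfg)$temp_c))
})

test_that("air noise has the configured AR(1) lag-1 autocorrelation", {
  cfg <- tiny_config(
    date_start = "2017-01-01", date_end = "2018-02-20", # > 10000 hours
    seasonal_mean = c(winter = 20, spring = 20, summer = 20, autumn = 20),
    diurnal_amplitude = c(winter = 0, spring = 0, summer = 0, autumn = 0),
    noise_sigma = 1, noise_phi = 0.6, seed = 5L
  )
  air <- generate_air_series(cfg)
  noise <- air$temp_c - 20
  rho <- stats::acf(noise, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(rho - 0.6), 0.05)
  expect_lt(abs(stats::sd(noise) - 1), 0.1) # sigma is the marginal SD
})

test_that("identity coupling reproduces the air series at every microsite", {
  cfg <- flat_config(exposure_profile = identity_profile(),
                     diurnal_amplitude = c(winter = 5, spring = 5,
                                           summer = 5, autumn = 5))
  air <- generate_air_series(cfg)
  ms <- generate_microsite_series(cfg, air)
  joined <- dplyr::inner_join(ms$records, air,
                              by = c("site", "timestamp"),
                              suffix = c("", "_air"))
  expect_equal(joined$temp_c, joined$temp_c_air)
  expect_true(all(ms$truth$slope == 1), info = "planted slopes recorded")
  expect_true(all(ms$truth$offset == 0))
})

test_that("a planted linear coupling is honoured exactly without noise", {
  cfg <- flat_config(
    exposure_profile = list(full_sun = c(slope = 0.5, offset = 5),
                            partial = c(slope = 0.5, offset = 5),
                            shade = c(slope = 0.5, offset = 5),
                            inside_vegetation = c(slope = 0.5, offset = 5)),
    seasonal_mean = c(winter = 30, spring = 30, summer = 30, autumn = 30)
  )
  air <- generate_air_series(cfg)
  ms <- generate_microsite_series(cfg, air)
  expect_true(all(ms$records$temp_c == 5 + 0.5 * 30)) # 20 degC everywhere
})

test_that("microsite generation fails loudly when air hours are missing", {
  cfg <- flat_config()
  air <- generate_air_series(cfg)
  gappy <- air[-c(10, 11), ]
  expect_error(generate_microsite_series(cfg, gappy), "missing",
               class = "thermoscape_data_error")
})

test_that("underground series honours its damping and lag limits", {
  cfg0 <- flat_config(diurnal_amplitude = c(winter = 8, spring = 8,
                                            summer = 8, autumn = 8),
                      underground_damping = 0, underground_lag = 0)
  air <- generate_air_series(cfg0)
  ug <- generate_underground_series(cfg0, air)
  daily_mean <- stats::ave(air$temp_c, date_of(air$timestamp), FUN = mean)
  expect_equal(ug$temp_c[seq_len(nrow(air))], daily_mean)

  cfg1 <- flat_config(diurnal_amplitude = c(winter = 8, spring = 8,
                                            summer = 8, autumn = 8),
                      underground_damping = 1, underground_lag = 0)
  air1 <- generate_air_series(cfg1)
  ug1 <- generate_underground_series(cfg1, air1)
  expect_equal(ug1$temp_c[seq_len(nrow(air1))], air1$temp_c)

  expect_error(tiny_config(underground_lag = 24), "underground_lag",
               class = "thermoscape_config_error")
})

test_that("damping scales the underground daily range proportionally", {
  cfg <- flat_config(diurnal_amplitude = c(winter = 10, spring = 10,
                                           summer = 10, autumn = 10),
                     underground_damping = 0.3, underground_lag = 0)
  air <- generate_air_series(cfg)
  ug <- generate_underground_series(cfg, air)
  rng <- function(x, day) tapply(x, day, function(v) max(v) - min(v))
  day <- date_of(air$timestamp)
  ratio <- rng(ug$temp_c[seq_len(nrow(air))], day) / rng(air$temp_c, day)
  expect_equal(as.numeric(ratio), rep(0.3, 7), tolerance = 1e-12)
})

test_that("righting trials are exact in the noiseless limit", {
  d <- righting_design(n_individuals = 4, reps_per_temp = 2, obs_sigma = 0,
                       body_temp_sigma = 0, failure_rule = function(t) 0,
                       seed = 9L)
  tr <- generate_righting_trials(d)
  expected <- 1 / flinn_eval(76.79, -4.45, 0.07, tr$treatment_c)
  expect_equal(tr$righting_time_s, expected)
  expect_equal(tr$body_temp_c, tr$treatment_c)
})

test_that("a certain failure rule yields no successful times at that temperature", {
  d <- righting_design(n_individuals = 10,
                       failure_rule = function(t) as.numeric(t == 10),
                       seed = 2L)
  tr <- generate_righting_trials(d)
  expect_true(all(is.na(tr$righting_time_s[tr$treatment_c == 10])))
  expect_true(any(!is.na(tr$righting_time_s[tr$treatment_c == 25])))
})

test_that("CSV fixtures round-trip and are byte-stable under a fixed seed", {
  cfg <- tiny_config(date_end = "2018-01-03")
  sc <- simulate_scenario(cfg, righting_design(n_individuals = 3, seed = 4L))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  paths <- write_scenario_csv(sc, dir1)
  write_scenario_csv(simulate_scenario(cfg, righting_design(n_individuals = 3,
                                                            seed = 4L)), dir2)
  for (p in names(paths)) {
    expect_identical(readLines(paths[[p]]),
                     readLines(file.path(dir2, basename(paths[[p]]))),
                     info = p)
  }
  back <- read_otm_tables(paths[["loggers"]], paths[["metadata"]],
                          paths[["events"]])
  merged <- dplyr::arrange(back$records, otm_id, timestamp)
  orig <- dplyr::arrange(sc$records, otm_id, timestamp)
  expect_equal(merged$temp_c, orig$temp_c, tolerance = 1e-12)
  expect_identical(merged$otm_id, orig$otm_id)
  expect_error(write_scenario_csv(sc, file.path(dir1, "nope")),
               class = "thermoscape_io_error")
})

test_that("generator schemas validate against ingest without special-casing", {
  cfg <- tiny_config(date_end = "2018-01-03")
  sc <- simulate_scenario(cfg)
  clean <- build_clean_dataset(sc$records, sc$events)
  expect_s3_class(clean, "clean_dataset")
  expect_true(all(c("date", "hour", "season") %in% names(clean$records)))
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_config(date_start = "2018-02-01", date_end = "2018-01-01"),
               class = "thermoscape_config_error")
  expect_error(tiny_config(otms_per_quadrat = 1),
               class = "thermoscape_config_error")
  expect_error(tiny_config(noise_phi = 1),
               class = "thermoscape_config_error")
  expect_error(tiny_config(exposure_profile = list(
    full_sun = c(slope = -1, offset = 0), partial = c(slope = 1, offset = 0),
    shade = c(slope = 1, offset = 0), inside_vegetation = c(slope = 1, offset = 0)
  )), class = "thermoscape_config_error")
})
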