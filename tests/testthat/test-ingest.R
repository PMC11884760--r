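make_hourly_records <- function(otm_id = "o1", date = as.Date("2018-01-03"),
                                hours = 0:23, temps = rep(20, length(hours))) {
  tibble::tibble(
    otm_id = otm_id,
    timestamp = as.POSIXct(paste(date, sprintf("%02d:00:00", hours)), tz = "UTC"),
    temp_c = temps,
    site = "s1", habitat = "native", quadrat_id = "q1",
    stratum = "ground", exposure = "full_sun"
  )
}

test_that("a service event removes the closed one-hour window around it", {
  rec <- dplyr::bind_rows(make_hourly_records("o1"), make_hourly_records("o2"))
  ev <- tibble::tibble(otm_id = "o1",
                       timestamp = as.POSIXct("2018-01-03 12:00:00", tz = "UTC"),
                       kind = "reprogram")
  out <- strip_service_windows(rec, ev, window_h = 1)
  gone <- setdiff(format(rec$timestamp[rec$otm_id == "o1"], "%H"),
                  format(out$timestamp[out$otm_id == "o1"], "%H"))
  expect_setequal(gone, c("11", "12", "13"))
  expect_equal(sum(out$otm_id == "o2"), 24) # other loggers untouched
  expect_equal(attr(out, "n_removed"), 3L)
})

test_that("no events leaves the dataset unchanged", {
  rec <- make_hourly_records()
  ev <- tibble::tibble(otm_id = character(),
                       timestamp = as.POSIXct(character(), tz = "UTC"),
                       kind = character())
  out <- strip_service_windows(rec, ev)
  expect_equal(nrow(out), nrow(rec))
  expect_equal(attr(out, "n_removed"), 0L)
})

test_that("overlapping service windows are unioned, not double counted", {
  rec <- make_hourly_records()
  ev <- tibble::tibble(
    otm_id = "o1",
    timestamp = as.POSIXct(c("2018-01-03 10:00:00", "2018-01-03 11:00:00"),
                           tz = "UTC"),
    kind = c("deploy", "reprogram")
  )
  out <- strip_service_windows(rec, ev, window_h = 1)
  # brute force: union of [event - 1h, event + 1h] over both events
  expected_gone <- sort(unique(unlist(lapply(ev$timestamp, function(t) {
    which(abs(as.numeric(difftime(rec$timestamp, t, units = "hours"))) <= 1)
  }))))
  expect_equal(attr(out, "n_removed"), length(expected_gone))
  expect_identical(out$timestamp, rec$timestamp[-expected_gone])
})

test_that("isolated spikes and out-of-bounds values are removed by rule", {
  rec <- make_hourly_records(hours = 0:3, temps = c(20, 21, 65, 22))
  out <- flag_outliers(rec, bounds = c(-10, 70), spike_delta = 20)
  expect_equal(out$temp_c, c(20, 21, 22))
  expect_equal(attr(out, "n_spikes"), 1L)

  smooth <- make_hourly_records(hours = 0:5, temps = c(20, 22, 24, 25, 24, 22))
  expect_equal(nrow(flag_outliers(smooth)), 6)

  oob <- make_hourly_records(hours = 0:2, temps = c(20, -50, 21))
  out2 <- flag_outliers(oob, bounds = c(-10, 70), spike_delta = 1000)
  expect_equal(attr(out2, "n_bounds"), 1L)
  expect_equal(out2$temp_c, c(20, 21))
})

test_that("exactly the planted spikes are removed from a smooth series", {
  hours <- 0:23
  base <- 20 + 5 * sin(2 * pi * hours / 24)
  rec <- dplyr::bind_rows(lapply(1:3, function(d) {
    make_hourly_records(sprintf("o%d", d), as.Date("2018-01-03") + d, hours, base)
  }))
  set.seed(1)
  idx <- sample(seq_len(nrow(rec))[c(-1, -nrow(rec))], 10)
  # keep planted spikes isolated from each other and from series edges
  idx <- idx[!duplicated(idx %/% 3)]
  rec$temp_c[idx] <- rec$temp_c[idx] + 40
  out <- flag_outliers(rec, bounds = c(-100, 100), spike_delta = 20)
  expect_equal(attr(out, "n_spikes"), length(idx))
  expect_equal(nrow(out), nrow(rec) - length(idx))
})

test_that("daytime restriction keeps 07:00-19:00 inclusive (13 samples/day)", {
  rec <- make_hourly_records()
  out <- restrict_daytime_window(rec)
  hrs <- as.integer(format(out$timestamp, "%H"))
  expect_setequal(hrs, 7:19)
  expect_equal(nrow(out), 13)
  expect_false(6 %in% hrs)
  expect_true(all(c(7, 19) %in% hrs))
})

test_that("date window restriction is inclusive and warns when empty", {
  rec <- dplyr::bind_rows(lapply(0:4, function(d) {
    make_hourly_records(date = as.Date("2018-01-01") + d, hours = 12)
  }))
  out <- restrict_daytime_window(rec, date_start = "2018-01-02",
                                 date_end = "2018-01-03")
  expect_equal(as.Date(format(out$timestamp, "%Y-%m-%d")),
               as.Date(c("2018-01-02", "2018-01-03")))
  expect_warning(restrict_daytime_window(rec, date_start = "2019-01-01"),
                 "no records")
})

test_that("austral seasons follow the month mapping", {
  expect_equal(as.character(assign_season(as.Date("2017-12-15"))), "summer")
  expect_equal(as.character(assign_season(as.Date("2018-01-20"))), "summer")
  expect_equal(as.character(assign_season(as.Date("2018-03-01"))), "autumn")
  expect_equal(as.character(assign_season(as.Date("2017-08-31"))), "winter")
  expect_equal(as.character(assign_season(as.Date("2017-09-01"))), "spring")
})

test_that("the cleaning pipeline equals manual composition and reconciles", {
  cfg <- tiny_config(date_end = "2018-01-05")
  sc <- simulate_scenario(cfg)
  # plant an out-of-bounds value
  sc$records$temp_c[100] <- 200
  clean <- build_clean_dataset(sc$records, sc$events)
  p <- clean$provenance
  expect_equal(p[["raw"]], p[["retained"]] + sum(p[2:6]))

  s1 <- strip_service_windows(sc$records, sc$events, 1)
  s2 <- flag_outliers(s1, c(-10, 70), 20)
  s3 <- restrict_daytime_window(s2, 7, 19)
  expect_equal(nrow(s3), p[["retained"]])
  expect_equal(sort(s3$temp_c), sort(clean$records$temp_c))
})

test_that("cleaning is idempotent on already-clean data", {
  cfg <- tiny_config(date_end = "2018-01-05")
  sc <- simulate_scenario(cfg)
  clean1 <- build_clean_dataset(sc$records, sc$events)
  clean2 <- build_clean_dataset(clean1$records[names(sc$records)], sc$events)
  expect_equal(clean2$records$temp_c, clean1$records$temp_c)
  expect_equal(clean2$provenance[["retained"]], clean1$provenance[["retained"]])
})

test_that("cleaning removes rows but never alters a temperature value", {
  cfg <- tiny_config(date_end = "2018-01-05")
  sc <- simulate_scenario(cfg)
  clean <- build_clean_dataset(sc$records, sc$events)
  key <- paste(clean$records$otm_id, clean$records$timestamp)
  raw_key <- paste(sc$records$otm_id, sc$records$timestamp)
  expect_true(all(key %in% raw_key))
  expect_equal(clean$records$temp_c, sc$records$temp_c[match(key, raw_key)])
})

test_that("table readers reject unknown loggers and duplicate timestamps", {
  cfg <- tiny_config(date_end = "2018-01-02")
  sc <- simulate_scenario(cfg)
  dir <- withr::local_tempdir()
  paths <- write_scenario_csv(sc, dir)

  meta <- readr::read_csv(paths[["metadata"]], show_col_types = FALSE)
  readr::write_csv(meta[-1, ], file.path(dir, "meta_missing.csv"))
  expect_error(read_otm_tables(paths[["loggers"]],
                               file.path(dir, "meta_missing.csv")),
               "without metadata", class = "thermoscape_data_error")

  log <- readr::read_csv(paths[["loggers"]], show_col_types = FALSE)
  readr::write_csv(dplyr::bind_rows(log, log[1, ]),
                   file.path(dir, "log_dup.csv"))
  expect_error(read_otm_tables(file.path(dir, "log_dup.csv"),
                               paths[["metadata"]]),
               "duplicated", class = "thermoscape_data_error")
})
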