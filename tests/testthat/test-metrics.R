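test_that("de index matches its defining formula on hand cases", {
  band <- paper_band()
  expect_equal(de_index(c(27, 30, 34), band), 0)
  expect_equal(de_index(c(25.2, 36.4), band), 1.5) # (1.0 + 2.0) / 2
  expect_equal(de_index(20.2, band), 6)
  expect_error(de_index(numeric(0), band), class = "thermoscape_data_error")
  # zero iff all temps inside the band
  expect_gt(de_index(c(30, 34.5), band), 0)
})

test_that("daily composition reduces quadrat-day pools correctly", {
  df <- tibble::tibble(otm_id = c("a", "b", "c"), quadrat_id = "q1",
                       habitat = "native", hour = c(9, 12, 15),
                       temp_c = c(20, 30, 40))
  rec <- records_from_table(df)
  out <- daily_composition(rec)
  vals <- setNames(out$value, out$metric)
  expect_equal(vals[["daily_median"]], 30)
  expect_equal(vals[["daily_min"]], 20)
  expect_equal(vals[["daily_max"]], 40)
  expect_equal(vals[["daily_range"]], 20)

  flat <- records_from_table(dplyr::mutate(df, temp_c = 25))
  expect_equal(daily_composition(flat)$value[
    daily_composition(flat)$metric == "daily_range"], 0)
})

test_that("hourly spatial range is the across-OTM span, needing two OTMs", {
  df <- tibble::tibble(otm_id = c("a", "b", "c"), quadrat_id = "q1",
                       habitat = "native", hour = 12,
                       temp_c = c(22, 30, 35))
  out <- hourly_spatial_range(records_from_table(df))
  expect_equal(out$value, 13)
  solo <- records_from_table(tibble::tibble(otm_id = "a", quadrat_id = "q2",
                                            habitat = "native", hour = 12,
                                            temp_c = 22))
  expect_equal(nrow(hourly_spatial_range(solo)), 0) # <2 OTMs skipped
  same <- records_from_table(dplyr::mutate(df, temp_c = 25))
  expect_equal(hourly_spatial_range(same)$value, 0)
})

test_that("minutes of optimal and detrimental exposure follow the set rules", {
  band <- paper_band()
  # OTM A within band at hours 9-11, OTM B within at 10-13: union is 5 hours
  df <- dplyr::bind_rows(
    tibble::tibble(otm_id = "A", quadrat_id = "q1", habitat = "native",
                   hour = 7:19, temp_c = ifelse(7:19 %in% 9:11, 30, 20)),
    tibble::tibble(otm_id = "B", quadrat_id = "q1", habitat = "native",
                   hour = 7:19, temp_c = ifelse(7:19 %in% 10:13, 30, 20))
  )
  rec <- records_from_table(df)
  expect_equal(minutes_any_within(rec, band)$value, 300)

  cold <- records_from_table(dplyr::mutate(df, temp_c = 10))
  expect_equal(minutes_any_within(cold, band)$value, 0)

  # 3 OTMs, 2 above the upper bound at noon: counts (2 >= ceil(3/2))
  df3 <- tibble::tibble(otm_id = c("a", "b", "c"), quadrat_id = "q1",
                        habitat = "native", hour = 12,
                        temp_c = c(40, 40, 30))
  expect_equal(minutes_half_beyond(records_from_table(df3), band, "above")$value,
               60)
  # 4 OTMs, only 1 above: does not count
  df4 <- tibble::tibble(otm_id = letters[1:4], quadrat_id = "q1",
                        habitat = "native", hour = 12,
                        temp_c = c(40, 30, 30, 30))
  expect_equal(minutes_half_beyond(records_from_table(df4), band, "above")$value,
               0)
})

test_that("band occupancy classifies exhaustively and sums to 100", {
  band <- paper_band()
  df <- tibble::tibble(otm_id = letters[1:4], quadrat_id = "q1",
                       habitat = "native", hour = 12,
                       temp_c = c(30, 30, 30, 40))
  occ <- band_occupancy(records_from_table(df), band)
  expect_equal(occ$pct_within, 75)
  expect_equal(occ$pct_above, 25)
  expect_equal(occ$pct_below, 0)

  all_in <- band_occupancy(records_from_table(
    dplyr::mutate(df, temp_c = 30)), band)
  expect_equal(all_in$pct_within, 100)
})

test_that("every metric equals a brute-force enumeration on the fixture", {
  band <- paper_band()
  rec <- metrics_fixture()
  ground <- rec[rec$stratum == "ground", ]
  ground$date <- as.Date(format(ground$timestamp, "%Y-%m-%d"))
  ground$hour <- as.integer(format(ground$timestamp, "%H"))

  # daily composition
  comp <- daily_composition(rec)
  for (q in unique(ground$quadrat_id)) {
    for (d in unique(ground$date)) {
      pool <- ground$temp_c[ground$quadrat_id == q & ground$date == d]
      sub <- comp[comp$quadrat_id == q & comp$date == d, ]
      expect_equal(sub$value[sub$metric == "daily_median"], median(pool))
      expect_equal(sub$value[sub$metric == "daily_range"], max(pool) - min(pool))
    }
  }

  # hourly spatial range, de, occupancy: loop over quadrat-hours
  sr <- hourly_spatial_range(rec)
  de <- hourly_de(rec, band)
  occ <- band_occupancy(rec, band)
  combos <- unique(ground[c("quadrat_id", "date", "hour")])
  for (i in seq_len(nrow(combos))) {
    sel <- ground$quadrat_id == combos$quadrat_id[i] &
      ground$date == combos$date[i] & ground$hour == combos$hour[i]
    temps <- ground$temp_c[sel]
    pick <- function(tb) tb[tb$quadrat_id == combos$quadrat_id[i] &
                              tb$date == combos$date[i] &
                              tb$hour == combos$hour[i], ]
    expect_equal(pick(sr)$value, max(temps) - min(temps))
    dev <- ifelse(temps < band$lower, band$lower - temps,
                  ifelse(temps > band$upper, temps - band$upper, 0))
    expect_equal(pick(de)$value, mean(dev))
    o <- pick(occ)
    expect_equal(o$pct_within + o$pct_above + o$pct_below, 100,
                 tolerance = 1e-9)
    expect_equal(o$pct_within, 100 * mean(temps >= band$lower &
                                            temps <= band$upper))
  }

  # minutes metrics: brute force per quadrat-day
  any_within <- minutes_any_within(rec, band)
  half_above <- minutes_half_beyond(rec, band, "above")
  half_below <- minutes_half_beyond(rec, band, "below")
  qd <- unique(ground[c("quadrat_id", "date")])
  for (i in seq_len(nrow(qd))) {
    sel <- ground[ground$quadrat_id == qd$quadrat_id[i] &
                    ground$date == qd$date[i], ]
    n_any <- n_above <- n_below <- 0
    for (h in unique(sel$hour)) {
      temps <- sel$temp_c[sel$hour == h]
      if (any(temps >= band$lower & temps <= band$upper)) n_any <- n_any + 1
      if (sum(temps > band$upper) >= ceiling(length(temps) / 2))
        n_above <- n_above + 1
      if (sum(temps < band$lower) >= ceiling(length(temps) / 2))
        n_below <- n_below + 1
    }
    pick <- function(tb) tb$value[tb$quadrat_id == qd$quadrat_id[i] &
                                    tb$date == qd$date[i]]
    expect_equal(pick(any_within), 60 * n_any)
    expect_equal(pick(half_above), 60 * n_above)
    expect_equal(pick(half_below), 60 * n_below)
  }
})

test_that("widening the band moves the minutes metrics monotonically", {
  rec <- metrics_fixture()
  narrow <- suitability_band(28, 32)
  wide <- suitability_band(24, 38)
  aw_n <- sum(minutes_any_within(rec, narrow)$value)
  aw_w <- sum(minutes_any_within(rec, wide)$value)
  expect_gte(aw_w, aw_n)
  for (side in c("above", "below")) {
    hb_n <- sum(minutes_half_beyond(rec, narrow, side)$value)
    hb_w <- sum(minutes_half_beyond(rec, wide, side)$value)
    expect_lte(hb_w, hb_n)
  }
  # minutes bounded by the daytime window
  expect_true(all(minutes_any_within(rec, wide)$value <= 60 * 13))
})

test_that("peak heat hour finds the forced afternoon maximum and breaks ties early", {
  cfg <- flat_config(diurnal_amplitude = c(winter = 10, spring = 10,
                                           summer = 10, autumn = 10))
  sc <- simulate_scenario(cfg)
  clean <- build_clean_dataset(sc$records, sc$events)
  pk <- peak_heat_hour(clean, stratum = "air")
  expect_equal(pk$peak_hour, 14) # half-sine forcing peaks at 14:00

  flat <- simulate_scenario(flat_config())
  clean_flat <- build_clean_dataset(flat$records, flat$events)
  pk_flat <- peak_heat_hour(clean_flat, stratum = "air")
  expect_equal(pk_flat$peak_hour, 7) # constant series: earliest hour wins

  # brute force on the fixture
  rec <- metrics_fixture()
  rec2 <- rec
  rec2$hour <- as.integer(format(rec2$timestamp, "%H"))
  air <- rec2[rec2$stratum == "air", ]
  meds <- tapply(air$temp_c, air$hour, median)
  expect_equal(peak_heat_hour(rec, "air")$peak_hour,
               as.integer(names(meds)[which.max(meds)]))
})
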