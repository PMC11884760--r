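#' Daily thermal composition per quadrat
#'
#' Pools all daytime samples of all OTMs of the requested stratum within each
#' quadrat-day and reports the daily median, minimum, maximum and range
#' (max - min) of temperature.
#'
#' @param dataset A `clean_dataset` or a cleaned records tibble.
#' @param stratum One of `"ground"`, `"underground"`, `"burrow"`.
#' @return A long tibble of metric rows: `metric`, `site`, `habitat`,
#'   `quadrat_id`, `stratum`, `season`, `date`, `value`, `n_otms`.
#' @export
daily_composition <- function(dataset, stratum = "ground") {
  stopifnot(stratum %in% c("ground", "underground", "burrow"))
  rec <- dplyr::filter(dataset_records(dataset), .data$stratum == !!stratum)
  rec |>
    dplyr::group_by(.data$site, .data$habitat, .data$quadrat_id, .data$stratum,
                    .data$season, .data$date) |>
    dplyr::summarise(
      daily_median = median(.data$temp_c),
      daily_min = min(.data$temp_c),
      daily_max = max(.data$temp_c),
      daily_range = max(.data$temp_c) - min(.data$temp_c),
      n_otms = dplyr::n_distinct(.data$otm_id),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(c("daily_median", "daily_min",
                                        "daily_max", "daily_range")),
                        names_to = "metric", values_to = "value") |>
    dplyr::relocate("metric")
}

#' Hourly spatial range of temperature within quadrats
#'
#' For every quadrat-hour with at least two ground OTMs reporting, the
#' difference between the warmest and coolest OTM: a measure of the spatial
#' thermal heterogeneity a thermoregulating animal can exploit at that
#' moment.
#'
#' @inheritParams daily_composition
#' @return Metric rows with `metric = "spatial_range"`, keyed by quadrat x
#'   date x hour.
#' @export
hourly_spatial_range <- function(dataset) {
  rec <- dplyr::filter(dataset_records(dataset), .data$stratum == "ground")
  rec |>
    dplyr::group_by(.data$site, .data$habitat, .data$quadrat_id, .data$stratum,
                    .data$season, .data$date, .data$hour) |>
    dplyr::summarise(
      value = max(.data$temp_c) - min(.data$temp_c),
      n_otms = dplyr::n_distinct(.data$otm_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_otms >= 2) |>
    dplyr::mutate(metric = "spatial_range") |>
    dplyr::relocate("metric")
}

#' Thermal habitat quality index de
#'
#' The mean absolute deviation of microsite temperatures from a suitability
#' band: temperatures inside the band deviate by zero, temperatures below it
#' by the distance to the lower bound, temperatures above it by the distance
#' to the upper bound. Values closer to zero indicate better thermal habitat
#' quality.
#'
#' @param temps Numeric vector of temperatures (degC).
#' @param band A [suitability_band()].
#' @return The de index (degC).
#' @examples
#' de_index(c(25.2, 36.4), suitability_band(26.2, 34.4)) # (1 + 2) / 2
#' @export
de_index <- function(temps, band) {
  stopifnot(inherits(band, "suitability_band"))
  if (length(temps) == 0) {
    abort("de_index needs at least one temperature",
          class = "thermoscape_data_error")
  }
  mean(band_deviation(temps, band))
}

band_deviation <- function(temps, band) {
  dplyr::case_when(
    temps < band$lower ~ band$lower - temps,
    temps > band$upper ~ temps - band$upper,
    .default = 0
  )
}

#' Hourly de index per quadrat
#'
#' Applies [de_index()] to the ground-OTM temperatures of every quadrat-hour.
#'
#' @inheritParams daily_composition
#' @param band A [suitability_band()].
#' @return Metric rows with `metric = "de"`, keyed by quadrat x date x hour.
#' @export
hourly_de <- function(dataset, band) {
  rec <- dplyr::filter(dataset_records(dataset), .data$stratum == "ground")
  rec |>
    dplyr::mutate(dev = band_deviation(.data$temp_c, band)) |>
    dplyr::group_by(.data$site, .data$habitat, .data$quadrat_id, .data$stratum,
                    .data$season, .data$date, .data$hour) |>
    dplyr::summarise(value = mean(.data$dev),
                     n_otms = dplyr::n_distinct(.data$otm_id),
                     .groups = "drop") |>
    dplyr::mutate(metric = "de") |>
    dplyr::relocate("metric")
}

#' Aggregate hourly de across quadrats and days
#'
#' Summarises the hourly de rows into the mean, minimum and maximum de per
#' habitat x season x hour -- the daily-course profile used to compare
#' habitat quality between native and invaded areas.
#'
#' @param de_rows Output of [hourly_de()].
#' @return A tibble with `habitat`, `season`, `hour`, `de_mean`, `de_min`,
#'   `de_max`, `n`.
#' @export
de_daily_profile <- function(de_rows) {
  de_rows |>
    dplyr::group_by(.data$habitat, .data$season, .data$hour) |>
    dplyr::summarise(de_mean = mean(.data$value), de_min = min(.data$value),
                     de_max = max(.data$value), n = dplyr::n(),
                     .groups = "drop")
}

#' Daily minutes with at least one optimal microsite
#'
#' For each quadrat-day, 60 minutes for every daytime hourly sample at which
#' at least one ground OTM of the quadrat lies within the suitability band
#' (an hourly sample stands for its whole hour).
#'
#' @inheritParams hourly_de
#' @return Metric rows with `metric = "minutes_any_within"` per quadrat-day.
#' @export
minutes_any_within <- function(dataset, band) {
  rec <- dplyr::filter(dataset_records(dataset), .data$stratum == "ground")
  rec |>
    dplyr::group_by(.data$site, .data$habitat, .data$quadrat_id, .data$stratum,
                    .data$season, .data$date, .data$hour) |>
    dplyr::summarise(
      any_within = any(.data$temp_c >= band$lower & .data$temp_c <= band$upper),
      n_otms = dplyr::n_distinct(.data$otm_id),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$site, .data$habitat, .data$quadrat_id, .data$stratum,
                    .data$season, .data$date) |>
    dplyr::summarise(value = 60 * sum(.data$any_within),
                     n_otms = max(.data$n_otms), .groups = "drop") |>
    dplyr::mutate(metric = "minutes_any_within") |>
    dplyr::relocate("metric")
}

#' Daily minutes with at least half the microsites beyond the band
#'
#' For each quadrat-day, 60 minutes for every hourly sample at which at least
#' half of the reporting ground OTMs (ceiling rule for odd counts: 2 of 3)
#' are above the band's upper bound (`side = "above"`) or below its lower
#' bound (`side = "below"`).
#'
#' @inheritParams hourly_de
#' @param side `"above"` or `"below"`.
#' @return Metric rows with `metric = "minutes_half_above"` or
#'   `"minutes_half_below"` per quadrat-day.
#' @export
minutes_half_beyond <- function(dataset, band, side = c("above", "below")) {
  side <- match.arg(side)
  rec <- dplyr::filter(dataset_records(dataset), .data$stratum == "ground")
  beyond <- if (side == "above") {
    function(t) t > band$upper
  } else {
    function(t) t < band$lower
  }
  rec |>
    dplyr::group_by(.data$site, .data$habitat, .data$quadrat_id, .data$stratum,
                    .data$season, .data$date, .data$hour) |>
    dplyr::summarise(
      half_beyond = sum(beyond(.data$temp_c)) >= ceiling(dplyr::n() / 2),
      n_otms = dplyr::n_distinct(.data$otm_id),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$site, .data$habitat, .data$quadrat_id, .data$stratum,
                    .data$season, .data$date) |>
    dplyr::summarise(value = 60 * sum(.data$half_beyond),
                     n_otms = max(.data$n_otms), .groups = "drop") |>
    dplyr::mutate(metric = paste0("minutes_half_", side)) |>
    dplyr::relocate("metric")
}

#' Percentage of OTMs within, above and below the band
#'
#' Classifies every ground OTM of every quadrat-hour into exactly one of
#' within / above / below the suitability band, yielding percentages that sum
#' to 100 per quadrat-hour.
#'
#' @inheritParams hourly_de
#' @return A tibble keyed by quadrat x date x hour with `pct_within`,
#'   `pct_above`, `pct_below`, `n_otms`.
#' @export
band_occupancy <- function(dataset, band) {
  rec <- dplyr::filter(dataset_records(dataset), .data$stratum == "ground")
  rec |>
    dplyr::group_by(.data$site, .data$habitat, .data$quadrat_id, .data$stratum,
                    .data$season, .data$date, .data$hour) |>
    dplyr::summarise(
      pct_within = 100 * mean(.data$temp_c >= band$lower &
                                .data$temp_c <= band$upper),
      pct_above = 100 * mean(.data$temp_c > band$upper),
      pct_below = 100 * mean(.data$temp_c < band$lower),
      n_otms = dplyr::n(),
      .groups = "drop"
    )
}

#' Aggregate band occupancy over the daily course
#'
#' Averages the occupancy percentages per habitat x season x hour, either by
#' pooling all OTM-hours (`method = "pool"`, each OTM-hour weighted equally)
#' or by averaging the per-quadrat-hour percentages (`method = "hours"`).
#'
#' @param dataset,band As in [band_occupancy()].
#' @param method `"pool"` or `"hours"`.
#' @return A tibble with `habitat`, `season`, `hour`, `pct_within`,
#'   `pct_above`, `pct_below`.
#' @export
band_occupancy_profile <- function(dataset, band, method = c("pool", "hours")) {
  method <- match.arg(method)
  if (method == "pool") {
    rec <- dplyr::filter(dataset_records(dataset), .data$stratum == "ground")
    rec |>
      dplyr::group_by(.data$habitat, .data$season, .data$hour) |>
      dplyr::summarise(
        pct_within = 100 * mean(.data$temp_c >= band$lower &
                                  .data$temp_c <= band$upper),
        pct_above = 100 * mean(.data$temp_c > band$upper),
        pct_below = 100 * mean(.data$temp_c < band$lower),
        .groups = "drop"
      )
  } else {
    band_occupancy(dataset, band) |>
      dplyr::group_by(.data$habitat, .data$season, .data$hour) |>
      dplyr::summarise(pct_within = mean(.data$pct_within),
                       pct_above = mean(.data$pct_above),
                       pct_below = mean(.data$pct_below),
                       .groups = "drop")
  }
}

#' Hour of peak heat per season
#'
#' The daytime hour with the highest median temperature over the season
#' (ties broken towards the earliest hour), computed from the requested
#' stratum, optionally per site.
#'
#' @inheritParams daily_composition
#' @param stratum Stratum to use (default `"air"`).
#' @param by_site Report per site instead of pooled.
#' @return A tibble with `season` (and `site` when `by_site`) and
#'   `peak_hour`.
#' @export
peak_heat_hour <- function(dataset, stratum = "air", by_site = FALSE) {
  rec <- dplyr::filter(dataset_records(dataset), .data$stratum == !!stratum)
  keys <- if (by_site) c("site", "season", "hour") else c("season", "hour")
  rec |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(med = median(.data$temp_c), .groups = "drop_last") |>
    dplyr::arrange(dplyr::desc(.data$med), .data$hour, .by_group = TRUE) |>
    dplyr::summarise(peak_hour = dplyr::first(.data$hour), .groups = "drop")
}

#' Compute the full suite of thermal-landscape metrics
#'
#' Convenience wrapper that stacks the daily composition (ground and
#' underground), the hourly spatial range, the hourly de index and the three
#' daily exposure-time metrics into one long table of metric rows.
#'
#' @inheritParams hourly_de
#' @return A long tibble of metric rows.
#' @export
landscape_metrics <- function(dataset, band) {
  strata <- intersect(c("ground", "underground", "burrow"),
                      unique(dataset_records(dataset)$stratum))
  dplyr::bind_rows(
    purrr::map_dfr(strata, function(s) daily_composition(dataset, s)),
    hourly_spatial_range(dataset),
    hourly_de(dataset, band),
    minutes_any_within(dataset, band),
    minutes_half_beyond(dataset, band, "above"),
    minutes_half_beyond(dataset, band, "below")
  )
}
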