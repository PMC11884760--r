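#' Generate the hourly air-temperature reference series
#'
#' One air logger per site, hourly over the configured date range. The series
#' is the seasonal nighttime baseline plus a half-sine diurnal wave over
#' 07:00--21:00 (peak 14:00) scaled by the seasonal amplitude, plus
#' stationary AR(1) noise.
#'
#' @param config A [scenario_config()].
#' @return A tibble of hourly records with columns `otm_id`, `timestamp`,
#'   `temp_c`, `site`, `habitat`, `quadrat_id`, `stratum` (`"air"`),
#'   `exposure`.
#' @export
generate_air_series <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  ts <- hourly_timestamps(config$date_start, config$date_end)
  hour <- hour_of(ts)
  season <- as.character(assign_season(date_of(ts)))
  forcing <- config$seasonal_mean[season] +
    config$diurnal_amplitude[season] * diurnal_phase(hour)
  withr::with_seed(config$seed, {
    purrr::map_dfr(scenario_sites(config), function(site) {
      tibble::tibble(
        otm_id = paste0(site, "_air"),
        timestamp = ts,
        temp_c = as.numeric(forcing) +
          ar1_noise(length(ts), config$noise_sigma, config$noise_phi),
        site = site,
        habitat = "native",
        quadrat_id = NA_character_,
        stratum = "air",
        exposure = "na"
      )
    })
  })
}

# check that `air` has every hour of the configured range for every site
check_air_coverage <- function(config, air) {
  need <- hourly_timestamps(config$date_start, config$date_end)
  for (site in scenario_sites(config)) {
    have <- air$timestamp[air$site == site & air$stratum == "air"]
    gaps <- need[!need %in% have]
    if (length(gaps) > 0) {
      abort(
        sprintf("air series for %s is missing %d hour(s), first gap %s",
                site, length(gaps), format(gaps[1])),
        class = "thermoscape_data_error"
      )
    }
  }
  invisible(TRUE)
}

#' Generate ground microsite series coupled to air temperature
#'
#' Each ground OTM gets an exposure class drawn from its habitat's mix, and a
#' true linear coupling `T_m(t) = offset + slope * T_air(t) + AR(1) noise`
#' taken from the class profile plus a small per-OTM jitter. The planted
#' slopes/offsets are returned as a truth table for recovery tests.
#'
#' @param config A [scenario_config()].
#' @param air Air series from [generate_air_series()] covering the range.
#' @return A list with `records` (tibble of OTM records, stratum `"ground"`)
#'   and `truth` (tibble: `otm_id`, `site`, `habitat`, `quadrat_id`,
#'   `exposure`, `slope`, `offset`).
#' @export
generate_microsite_series <- function(config, air) {
  stopifnot(inherits(config, "scenario_config"))
  check_air_coverage(config, air)
  air <- dplyr::arrange(air, .data$site, .data$timestamp)

  withr::with_seed(config$seed + 1L, {
    design <- tidyr::expand_grid(
      site = scenario_sites(config),
      habitat = habitat_levels(),
      quadrat = seq_len(config$quadrats_per_habitat),
      otm = seq_len(config$otms_per_quadrat)
    )
    design <- dplyr::mutate(
      design,
      quadrat_id = sprintf("%s_%s_q%d", .data$site, .data$habitat, .data$quadrat),
      otm_id = sprintf("%s_g%d", .data$quadrat_id, .data$otm)
    )
    # exposure classes are drawn per OTM from the habitat's availability mix,
    # but a quadrat is never all one class when the mix offers alternatives:
    # field placement deliberately sampled microsites differing in exposure
    quadrat_classes <- function(h, n) {
      mix <- config$exposure_mix[[h]]
      mix <- mix[mix > 0]
      cls <- sample(names(mix), n, replace = TRUE, prob = mix)
      if (length(unique(cls)) == 1 && length(mix) > 1) {
        others <- mix[names(mix) != cls[1]]
        cls[n] <- sample(names(others), 1, prob = others)
      }
      cls
    }
    by_quadrat <- split(seq_len(nrow(design)),
                        list(design$quadrat_id), drop = TRUE)
    classes <- character(nrow(design))
    for (idx in by_quadrat) {
      classes[idx] <- quadrat_classes(design$habitat[idx[1]], length(idx))
    }
    base <- purrr::map(classes, function(cl) config$exposure_profile[[cl]])
    truth <- dplyr::mutate(
      design,
      exposure = classes,
      slope = pmax(0.05, purrr::map_dbl(base, "slope") +
                     rnorm(nrow(design), 0, config$slope_jitter_sd)),
      offset = purrr::map_dbl(base, "offset") +
        rnorm(nrow(design), 0, config$offset_jitter_sd)
    )
    truth <- dplyr::select(truth, "otm_id", "site", "habitat", "quadrat_id",
                           "exposure", "slope", "offset")

    air_by_site <- split(air, air$site)
    records <- purrr::pmap_dfr(truth, function(otm_id, site, habitat, quadrat_id,
                                               exposure, slope, offset) {
      a <- air_by_site[[site]]
      tibble::tibble(
        otm_id = otm_id,
        timestamp = a$timestamp,
        temp_c = offset + slope * a$temp_c +
          ar1_noise(nrow(a), config$noise_sigma, config$noise_phi),
        site = site,
        habitat = habitat,
        quadrat_id = quadrat_id,
        stratum = "ground",
        exposure = exposure
      )
    })
    list(records = records, truth = truth)
  })
}

#' Generate damped, lagged underground series
#'
#' Belowground temperature at nesting depth is emulated as the running daily
#' mean of air temperature plus a damped, lagged diurnal anomaly:
#' `T_u(t) = mean_day(t) + damping * (T_air(t - lag) - mean_day(t - lag)) + noise`.
#' With damping 1 and lag 0 this reduces to the air series; with damping 0 it
#' is the flat daily mean.
#'
#' @inheritParams generate_microsite_series
#' @return A tibble of OTM records with stratum `"underground"`.
#' @export
generate_underground_series <- function(config, air) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$underground_lag >= 24) {
    abort("underground_lag must be < 24 h", class = "thermoscape_config_error")
  }
  check_air_coverage(config, air)
  air <- dplyr::arrange(air, .data$site, .data$timestamp)

  withr::with_seed(config$seed + 2L, {
    air_by_site <- split(air, air$site)
    design <- tidyr::expand_grid(
      site = scenario_sites(config),
      habitat = habitat_levels(),
      quadrat = seq_len(config$underground_per_habitat)
    )
    purrr::pmap_dfr(design, function(site, habitat, quadrat) {
      a <- air_by_site[[site]]
      day <- date_of(a$timestamp)
      daily_mean <- stats::ave(a$temp_c, day, FUN = mean)
      anom <- a$temp_c - daily_mean
      lag <- config$underground_lag
      lagged_anom <- dplyr::lag(anom, lag, default = 0)
      quadrat_id <- sprintf("%s_%s_q%d", site, habitat, quadrat)
      tibble::tibble(
        otm_id = sprintf("%s_ug", quadrat_id),
        timestamp = a$timestamp,
        temp_c = daily_mean + config$underground_damping * lagged_anom +
          ar1_noise(nrow(a), config$noise_sigma, config$noise_phi),
        site = site,
        habitat = habitat,
        quadrat_id = quadrat_id,
        stratum = "underground",
        exposure = "na"
      )
    })
  })
}

#' Service-event log for a simulated deployment
#'
#' Loggers are deployed at the start of the record and revisited for
#' reprogramming every `every_days` days at noon, mirroring quarterly field
#' service of memory-limited loggers.
#'
#' @param config A [scenario_config()].
#' @param otm_ids Character vector of logger ids to emit events for.
#' @param every_days Days between reprogramming visits.
#' @return A tibble with `otm_id`, `timestamp`, `kind` (`deploy`/`reprogram`).
#' @export
generate_service_events <- function(config, otm_ids, every_days = 90) {
  deploy <- as.POSIXct(paste(config$date_start, "09:00:00"), tz = "UTC")
  visits <- if (config$date_start + every_days <= config$date_end) {
    seq(config$date_start + every_days, config$date_end, by = every_days)
  } else {
    as.Date(character())
  }
  tidyr::expand_grid(otm_id = unique(otm_ids), visit = c(config$date_start, visits)) |>
    dplyr::mutate(
      kind = ifelse(.data$visit == config$date_start, "deploy", "reprogram"),
      timestamp = as.POSIXct(paste(.data$visit, "12:00:00"), tz = "UTC")
    ) |>
    dplyr::mutate(timestamp = dplyr::if_else(.data$kind == "deploy",
                                             deploy, .data$timestamp)) |>
    dplyr::select("otm_id", "timestamp", "kind") |>
    dplyr::arrange(.data$otm_id, .data$timestamp)
}

#' Simulate a complete synthetic study
#'
#' Runs the air, ground-microsite and underground generators, builds the
#' service-event log and (optionally) righting trials, and returns everything
#' needed to exercise the full pipeline, including the planted ground truth.
#'
#' @param config A [scenario_config()].
#' @param design Optional [righting_design()]; `NULL` skips trials.
#' @return A list of class `thermoscape_scenario` with elements `records`
#'   (all strata, including air), `truth`, `events`, `trials` (or `NULL`),
#'   `config` and `design`.
#' @export
simulate_scenario <- function(config, design = NULL) {
  air <- generate_air_series(config)
  ground <- generate_microsite_series(config, air)
  underground <- generate_underground_series(config, air)
  records <- dplyr::bind_rows(air, ground$records, underground)
  events <- generate_service_events(config, unique(records$otm_id))
  trials <- if (!is.null(design)) generate_righting_trials(design) else NULL
  structure(
    list(records = records, truth = ground$truth, events = events,
         trials = trials, config = config, design = design),
    class = "thermoscape_scenario"
  )
}

#' @export
print.thermoscape_scenario <- function(x, ...) {
  cat("<thermoscape_scenario>\n")
  cat(sprintf("  %d hourly records from %d loggers (%s strata)\n",
              nrow(x$records), dplyr::n_distinct(x$records$otm_id),
              paste(unique(x$records$stratum), collapse = "/")))
  if (!is.null(x$trials)) {
    cat(sprintf("  %d righting trials from %d individuals\n",
                nrow(x$trials), dplyr::n_distinct(x$trials$individual_id)))
  }
  invisible(x)
}

#' Write a scenario to CSV fixture files
#'
#' Writes `loggers.csv`, `metadata.csv`, `events.csv`, `truth.csv` and, when
#' trials exist, `trials.csv` with the schemas expected by [read_otm_tables()]
#' and [read_trials()].
#'
#' @param scenario A [simulate_scenario()] result.
#' @param dir Existing writable directory.
#' @return Invisibly, the named vector of paths written.
#' @export
write_scenario_csv <- function(scenario, dir) {
  stopifnot(inherits(scenario, "thermoscape_scenario"))
  if (!dir.exists(dir)) {
    abort(sprintf("directory does not exist: %s", dir),
          class = "thermoscape_io_error")
  }
  iso <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S")
  paths <- c(
    loggers = file.path(dir, "loggers.csv"),
    metadata = file.path(dir, "metadata.csv"),
    events = file.path(dir, "events.csv"),
    truth = file.path(dir, "truth.csv")
  )
  loggers <- scenario$records |>
    dplyr::transmute(.data$otm_id, timestamp = iso(.data$timestamp), .data$temp_c)
  metadata <- scenario$records |>
    dplyr::distinct(.data$otm_id, .data$site, .data$habitat, .data$quadrat_id,
                    .data$stratum, .data$exposure)
  events <- dplyr::mutate(scenario$events, timestamp = iso(.data$timestamp))
  readr::write_csv(loggers, paths[["loggers"]])
  readr::write_csv(metadata, paths[["metadata"]])
  readr::write_csv(events, paths[["events"]])
  readr::write_csv(scenario$truth, paths[["truth"]])
  if (!is.null(scenario$trials)) {
    paths <- c(paths, trials = file.path(dir, "trials.csv"))
    readr::write_csv(scenario$trials, paths[["trials"]])
  }
  invisible(paths)
}
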