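#' Scenario configuration for the synthetic microclimate generator
#'
#' Bundles every knob of the synthetic thermal-landscape generator into a
#' validated list. The defaults emulate the field design the package targets:
#' four study sites, native and tree-invaded areas sampled with five quadrats
#' per habitat carrying three operative-temperature models (OTMs) each at
#' ground level, a buried sensor in three quadrats per habitat, and one air
#' logger per site, all recording hourly over a full year.
#'
#' Air temperature is forced as a seasonal baseline plus a half-sine diurnal
#' wave over 07:00--21:00 peaking at 14:00, with stationary AR(1) noise.
#' Ground microsites are linearly coupled to air temperature with an
#' exposure-class-specific slope and offset: sun-exposed classes amplify
#' (slope > 1) and shaded classes buffer (slope < 1). Underground series are
#' the running daily mean plus a damped, lagged anomaly.
#'
#' @param n_sites Number of study sites.
#' @param quadrats_per_habitat Quadrats per site x habitat.
#' @param otms_per_quadrat Ground OTMs per quadrat (at least 2).
#' @param underground_per_habitat Quadrats per site x habitat that also carry
#'   one buried sensor.
#' @param date_start,date_end Calendar dates bounding the simulated record.
#' @param seasonal_mean Named numeric, nighttime baseline air temperature
#'   (degC) per season (`winter`, `spring`, `summer`, `autumn`).
#' @param diurnal_amplitude Named numeric, peak daytime rise above the
#'   baseline (degC) per season.
#' @param exposure_profile Named list mapping exposure class to
#'   `c(slope, offset)` of the linear coupling to air temperature.
#' @param exposure_mix Named list with elements `native` and `invaded`, each a
#'   named probability vector over exposure classes. Defaults are sun-heavy
#'   for native shrubland and shade-heavy under invasive tree stands.
#' @param slope_jitter_sd,offset_jitter_sd Per-OTM Gaussian jitter applied to
#'   the class slope/offset so OTMs within a class are not identical.
#' @param underground_damping Fraction (0--1) of the air diurnal anomaly
#'   transmitted belowground.
#' @param underground_lag Lag (whole hours, < 24) of the belowground anomaly.
#' @param noise_sigma Stationary standard deviation (degC) of the AR(1)
#'   logger/microsite noise.
#' @param noise_phi AR(1) lag-1 coefficient in [0, 1).
#' @param seed Integer seed; the same config and seed reproduce the same data.
#'
#' @return A list of class `scenario_config`.
#' @seealso [simulate_scenario()], [generate_air_series()]
#' @export
scenario_config <- function(n_sites = 4,
                            quadrats_per_habitat = 5,
                            otms_per_quadrat = 3,
                            underground_per_habitat = 3,
                            date_start = as.Date("2017-08-01"),
                            date_end = as.Date("2018-07-31"),
                            seasonal_mean = c(winter = 10, spring = 15,
                                              summer = 22, autumn = 15),
                            diurnal_amplitude = c(winter = 6, spring = 10,
                                                  summer = 13, autumn = 10),
                            exposure_profile = list(
                              full_sun = c(slope = 1.5, offset = -6),
                              partial = c(slope = 1.2, offset = -2),
                              shade = c(slope = 0.9, offset = 0.5),
                              inside_vegetation = c(slope = 0.75, offset = 2)
                            ),
                            exposure_mix = list(
                              native = c(full_sun = 0.40, partial = 0.40,
                                         shade = 0.15, inside_vegetation = 0.05),
                              invaded = c(full_sun = 0.05, partial = 0.30,
                                          shade = 0.40, inside_vegetation = 0.25)
                            ),
                            slope_jitter_sd = 0.05,
                            offset_jitter_sd = 0.5,
                            underground_damping = 0.3,
                            underground_lag = 2,
                            noise_sigma = 1,
                            noise_phi = 0.6,
                            seed = 1L) {
  date_start <- as.Date(date_start)
  date_end <- as.Date(date_end)
  if (is.na(date_start) || is.na(date_end) || date_end <= date_start) {
    abort("`date_end` must be after `date_start`",
          class = "thermoscape_config_error")
  }
  check_scalar_number(n_sites, "n_sites", 1)
  check_scalar_number(quadrats_per_habitat, "quadrats_per_habitat", 1)
  check_scalar_number(otms_per_quadrat, "otms_per_quadrat", 2)
  check_scalar_number(underground_per_habitat, "underground_per_habitat", 0,
                      quadrats_per_habitat)
  check_scalar_number(underground_damping, "underground_damping", 0, 1)
  check_scalar_number(underground_lag, "underground_lag", 0, 23)
  check_scalar_number(noise_sigma, "noise_sigma", 0)
  if (!is.numeric(noise_phi) || noise_phi < 0 || noise_phi >= 1) {
    abort("`noise_phi` must lie in [0, 1)", class = "thermoscape_config_error")
  }
  for (s in season_levels()) {
    if (!s %in% names(seasonal_mean) || !s %in% names(diurnal_amplitude)) {
      abort(sprintf("seasonal_mean and diurnal_amplitude need a `%s` entry", s),
            class = "thermoscape_config_error")
    }
  }
  slopes <- vapply(exposure_profile, function(p) p[["slope"]], numeric(1))
  if (any(slopes <= 0)) {
    abort("all exposure-profile slopes must be > 0",
          class = "thermoscape_config_error")
  }
  for (h in habitat_levels()) {
    mix <- exposure_mix[[h]]
    if (is.null(mix) || any(mix < 0) || sum(mix) <= 0 ||
        !all(names(mix) %in% names(exposure_profile))) {
      abort(sprintf("exposure_mix$%s must be nonnegative weights over profile classes", h),
            class = "thermoscape_config_error")
    }
  }
  structure(
    list(
      n_sites = as.integer(n_sites),
      quadrats_per_habitat = as.integer(quadrats_per_habitat),
      otms_per_quadrat = as.integer(otms_per_quadrat),
      underground_per_habitat = as.integer(underground_per_habitat),
      date_start = date_start, date_end = date_end,
      seasonal_mean = seasonal_mean,
      diurnal_amplitude = diurnal_amplitude,
      exposure_profile = exposure_profile,
      exposure_mix = exposure_mix,
      slope_jitter_sd = slope_jitter_sd,
      offset_jitter_sd = offset_jitter_sd,
      underground_damping = underground_damping,
      underground_lag = as.integer(underground_lag),
      noise_sigma = noise_sigma,
      noise_phi = noise_phi,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d sites, %d quadrats/habitat, %d OTMs/quadrat\n",
              x$n_sites, x$quadrats_per_habitat, x$otms_per_quadrat))
  cat(sprintf("  %s to %s, noise sigma %.2f degC (AR1 phi %.2f), seed %d\n",
              x$date_start, x$date_end, x$noise_sigma, x$noise_phi, x$seed))
  invisible(x)
}

scenario_sites <- function(config) sprintf("site%02d", seq_len(config$n_sites))

# diurnal phase: half-sine over 07:00-21:00 local, peaking at 14:00
diurnal_phase <- function(hour) {
  ifelse(hour >= 7 & hour <= 21, sin(pi * (hour - 7) / 14), 0)
}
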