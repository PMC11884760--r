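# Shared fixture builders. Everything is generated in code at test time.

tiny_config <- function(...) {
  defaults <- list(
    n_sites = 1, quadrats_per_habitat = 2, otms_per_quadrat = 3,
    underground_per_habitat = 1,
    date_start = "2018-01-01", date_end = "2018-01-07",
    seed = 42L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}

# a perfectly quiet configuration: constant 20 degC air, no noise
flat_config <- function(...) {
  quiet <- list(
    seasonal_mean = c(winter = 20, spring = 20, summer = 20, autumn = 20),
    diurnal_amplitude = c(winter = 0, spring = 0, summer = 0, autumn = 0),
    noise_sigma = 0, slope_jitter_sd = 0, offset_jitter_sd = 0
  )
  do.call(tiny_config, utils::modifyList(quiet, list(...)))
}

# exposure profile where every class is the identity coupling
identity_profile <- function() {
  list(full_sun = c(slope = 1, offset = 0),
       partial = c(slope = 1, offset = 0),
       shade = c(slope = 1, offset = 0),
       inside_vegetation = c(slope = 1, offset = 0))
}

paper_band <- function() suitability_band(26.2, 34.4)

# hand-build a cleaned records tibble from (otm, quadrat, habitat, hour, temp)
records_from_table <- function(df, site = "s1", date = as.Date("2018-01-03"),
                               stratum = "ground") {
  tibble::tibble(
    otm_id = df$otm_id,
    timestamp = as.POSIXct(paste(date, sprintf("%02d:00:00", df$hour)),
                           tz = "UTC"),
    temp_c = df$temp_c,
    site = site,
    habitat = df$habitat %||% "native",
    quadrat_id = df$quadrat_id,
    stratum = stratum,
    exposure = "full_sun",
    date = date,
    hour = df$hour,
    season = assign_season(date)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

date_of <- function(ts) as.Date(format(ts, "%Y-%m-%d"))

# year-long two-site invasion scenario: native quadrats carry only
# amplifying sun-exposed classes (slopes > 1), invaded quadrats only
# buffering shaded classes (slopes < 1)
planted_invasion_config <- function(...) {
  tiny_config(
    n_sites = 2, quadrats_per_habitat = 3, otms_per_quadrat = 3,
    underground_per_habitat = 2,
    date_start = "2017-10-01", date_end = "2018-09-30",
    exposure_mix = list(
      native = c(full_sun = 0.65, partial = 0.35, shade = 0,
                 inside_vegetation = 0),
      invaded = c(full_sun = 0, partial = 0, shade = 0.55,
                  inside_vegetation = 0.45)
    ),
    ...
  )
}

# A small deterministic fixture: 2 quadrats x 3 OTMs x 7 days x 13 daytime
# hours of ground data plus an air series, with varied temperatures.
metrics_fixture <- function() {
  days <- as.Date("2018-01-01") + 0:6
  grid <- expand.grid(quadrat = 1:2, otm = 1:3, day = seq_along(days),
                      hour = 7:19)
  temp <- 15 +
    10 * sin(pi * (grid$hour - 7) / 14) * grid$quadrat + # quadrat 2 hotter
    2 * grid$otm +                                       # spread across OTMs
    0.5 * grid$day +                                     # slow seasonal drift
    3 * sin(grid$hour * grid$otm)                        # deterministic wiggle
  ground <- tibble::tibble(
    otm_id = sprintf("q%d_o%d", grid$quadrat, grid$otm),
    timestamp = as.POSIXct(paste(days[grid$day],
                                 sprintf("%02d:00:00", grid$hour)), tz = "UTC"),
    temp_c = temp,
    site = "s1",
    habitat = ifelse(grid$quadrat == 1, "invaded", "native"),
    quadrat_id = sprintf("q%d", grid$quadrat),
    stratum = "ground", exposure = "partial"
  )
  air <- tibble::tibble(
    otm_id = "s1_air",
    timestamp = as.POSIXct(paste(rep(days, each = 13),
                                 sprintf("%02d:00:00", 7:19)), tz = "UTC"),
    temp_c = 15 + 8 * sin(pi * (rep(7:19, times = 7) - 7) / 14),
    site = "s1", habitat = "native", quadrat_id = NA_character_,
    stratum = "air", exposure = "na"
  )
  dplyr::bind_rows(ground, air)
}

# simulate metric rows with controllable variance components
sim_metric_rows <- function(n_sites = 4, n_quadrats = 3, n_days = 15,
                            habitat_effect = 0, site_sd = 0, quadrat_sd = 0,
                            resid_sd = 1, seasons = "summer", seed = 1) {
  set.seed(seed)
  grid <- expand.grid(site = sprintf("s%d", seq_len(n_sites)),
                      habitat = c("native", "invaded"),
                      quadrat = seq_len(n_quadrats),
                      season = seasons,
                      day = seq_len(n_days),
                      stringsAsFactors = FALSE)
  site_fx <- rnorm(n_sites, 0, site_sd)
  names(site_fx) <- sprintf("s%d", seq_len(n_sites))
  grid$quadrat_id <- paste(grid$site, grid$habitat, grid$quadrat, sep = "_")
  quadrat_fx <- rnorm(length(unique(grid$quadrat_id)), 0, quadrat_sd)
  names(quadrat_fx) <- unique(grid$quadrat_id)
  grid$value <- 20 + habitat_effect * (grid$habitat == "invaded") +
    site_fx[grid$site] + quadrat_fx[grid$quadrat_id] +
    rnorm(nrow(grid), 0, resid_sd)
  tibble::as_tibble(grid)
}
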