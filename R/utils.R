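#' Assign austral season from a timestamp or date
#'
#' Months are mapped to the austral seasons used throughout the package:
#' June--August is winter, September--November spring, December--February
#' summer and March--May autumn. Note that December and the following
#' January--February fall in the same season even though they belong to
#' different calendar years.
#'
#' @param x A `Date`, `POSIXct` or anything `as.Date()` understands.
#' @return A factor with levels `winter`, `spring`, `summer`, `autumn`.
#' @examples
#' assign_season(as.Date(c("2017-12-15", "2018-03-01", "2017-08-31")))
#' @export
assign_season <- function(x) {
  m <- as.integer(format(as.Date(x), "%m"))
  s <- dplyr::case_when(
    m %in% 6:8 ~ "winter",
    m %in% 9:11 ~ "spring",
    m %in% c(12L, 1L, 2L) ~ "summer",
    m %in% 3:5 ~ "autumn"
  )
  factor(s, levels = season_levels())
}

season_levels <- function() c("winter", "spring", "summer", "autumn")

habitat_levels <- function() c("native", "invaded")

stratum_levels <- function() c("ground", "underground", "burrow", "air")

exposure_levels <- function() {
  c("full_sun", "partial", "shade", "inside_vegetation", "na")
}

# hour-of-day as integer 0-23 from a POSIXct on the logger's local clock
hour_of <- function(ts) as.integer(format(ts, "%H"))

date_of <- function(ts) as.Date(format(ts, "%Y-%m-%d"))

# all hourly timestamps covering [date_start, date_end], naive local clock (UTC storage)
hourly_timestamps <- function(date_start, date_end) {
  seq(
    from = as.POSIXct(paste(date_start, "00:00:00"), tz = "UTC"),
    to = as.POSIXct(paste(date_end, "23:00:00"), tz = "UTC"),
    by = "hour"
  )
}

# stationary AR(1) noise with marginal sd `sigma` and lag-1 correlation `phi`
ar1_noise <- function(n, sigma, phi) {
  if (sigma == 0 || n == 0) return(numeric(n))
  innov_sd <- sigma * sqrt(1 - phi^2)
  e <- rnorm(n, 0, innov_sd)
  e[1] <- rnorm(1, 0, sigma) # stationary start
  if (phi == 0) return(e)
  as.numeric(stats::filter(e, phi, method = "recursive", init = 0))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
          class = "thermoscape_config_error")
  }
  invisible(x)
}
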