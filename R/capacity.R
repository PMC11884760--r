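#' Pair microsite records with the site's hourly air series
#'
#' Joins every ground/underground/burrow sample with the air temperature
#' recorded at the same site and hour, producing the paired hourly series the
#' buffering/amplifying analysis is built on. Hours without an air reading
#' are dropped (count attached as attribute `n_unmatched`).
#'
#' @param dataset A `clean_dataset` or cleaned records tibble containing both
#'   microsite and air strata.
#' @return A tibble with `site`, `habitat`, `quadrat_id`, `stratum`,
#'   `season`, `otm_id`, `date`, `hour`, `temp_c` (microsite) and `air_c`.
#' @export
pair_with_air <- function(dataset) {
  rec <- dataset_records(dataset)
  air <- rec |>
    dplyr::filter(.data$stratum == "air") |>
    dplyr::group_by(.data$site, .data$date, .data$hour) |>
    dplyr::summarise(air_c = mean(.data$temp_c), .groups = "drop")
  micro <- dplyr::filter(rec, .data$stratum != "air")
  missing_air <- setdiff(unique(micro$site), unique(air$site))
  if (length(missing_air) > 0) {
    abort(sprintf("no air series for site(s): %s",
                  paste(missing_air, collapse = ", ")),
          class = "thermoscape_data_error")
  }
  paired <- dplyr::inner_join(micro, air, by = c("site", "date", "hour"))
  structure(
    dplyr::select(paired, "site", "habitat", "quadrat_id", "stratum",
                  "season", "otm_id", "date", "hour", "temp_c", "air_c"),
    n_unmatched = nrow(micro) - nrow(paired)
  )
}

#' Fit the microsite-versus-air coupling slope
#'
#' Linear mixed model with hourly microsite temperature as the response,
#' hourly air temperature as the fixed explanatory variable, and a random
#' intercept for day. Slopes below one indicate buffering, above one
#' amplifying. When fewer than two days are available or the random-effect
#' fit is singular, the model falls back to ordinary least squares and the
#' result is flagged (`method = "ols"`).
#'
#' @param pairs A tibble with `temp_c`, `air_c` and `date` (day grouping).
#' @return A one-row tibble: `slope`, `intercept`, `slope_se`, `n_pairs`,
#'   `n_days`, `method`, `air_min`, `air_max`.
#' @export
fit_air_coupling <- function(pairs) {
  pairs <- pairs[is.finite(pairs$temp_c) & is.finite(pairs$air_c), ]
  if (nrow(pairs) < 10) {
    abort(sprintf("need at least 10 paired hours, got %d", nrow(pairs)),
          class = "thermoscape_data_error")
  }
  n_days <- dplyr::n_distinct(pairs$date)
  method <- "lmm"
  fit <- NULL
  est <- NULL
  if (n_days >= 2) {
    est <- tryCatch(suppressWarnings({
      fit <- suppressMessages(lme4::lmer(temp_c ~ air_c + (1 | date),
                                         data = pairs, REML = TRUE))
      if (lme4::isSingular(fit, tol = 1e-5)) {
        NULL
      } else {
        se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["air_c"]]
        if (!is.finite(se)) NULL else list(cf = lme4::fixef(fit), se = se)
      }
    }), error = function(e) NULL)
  }
  if (is.null(est)) {
    method <- "ols"
    fit <- lm(temp_c ~ air_c, data = pairs)
    est <- suppressWarnings(
      list(cf = coef(fit),
           se = summary(fit)$coefficients["air_c", "Std. Error"])
    )
  }
  cf <- est$cf
  se <- est$se
  tibble::tibble(
    slope = unname(cf[["air_c"]]),
    intercept = unname(cf[["(Intercept)"]]),
    slope_se = se,
    n_pairs = nrow(pairs),
    n_days = n_days,
    method = method,
    air_min = min(pairs$air_c),
    air_max = max(pairs$air_c)
  )
}

#' Signed areas between a fitted coupling line and the unity line
#'
#' The deviation of the fitted line from the unity line is
#' `d(x) = intercept + (slope - 1) x`. Integrating `d` analytically over the
#' air-temperature range, the positive part is the amplifying area (>= 0),
#' the negative part the buffering area (<= 0), and their sum the total
#' modifying capacity (degC^2). When the line crosses unity strictly inside
#' the range the integral is split exactly at the crossing
#' `x* = intercept / (1 - slope)`; a crossing at a boundary contributes to
#' neither side.
#'
#' @param slope,intercept Fitted line coefficients.
#' @param air_min,air_max Integration range (swapped if given in reverse).
#' @return A one-row tibble: `slope`, `intercept`, `air_min`, `air_max`,
#'   `area_amplify`, `area_buffer`, `total_capacity`.
#' @examples
#' modifying_areas(0.5, 0, 0, 10) # buffering triangle, total -25
#' @export
modifying_areas <- function(slope, intercept, air_min, air_max) {
  if (air_min > air_max) {
    tmp <- air_min; air_min <- air_max; air_max <- tmp
  }
  if (air_min == air_max) {
    abort("air_min and air_max must differ", class = "thermoscape_config_error")
  }
  # antiderivative of d(x) = intercept + (slope - 1) x
  D <- function(x) intercept * x + (slope - 1) * x^2 / 2
  seg <- function(x1, x2) D(x2) - D(x1)
  cuts <- c(air_min, air_max)
  if (slope != 1) {
    xstar <- intercept / (1 - slope)
    if (xstar > air_min && xstar < air_max) cuts <- c(air_min, xstar, air_max)
  }
  areas <- vapply(seq_len(length(cuts) - 1),
                  function(i) seg(cuts[i], cuts[i + 1]), numeric(1))
  tibble::tibble(
    slope = slope, intercept = intercept,
    air_min = air_min, air_max = air_max,
    area_amplify = sum(pmax(areas, 0)),
    area_buffer = sum(pmin(areas, 0)),
    total_capacity = sum(areas)
  )
}

#' Buffering/amplifying capacity across the study design
#'
#' Runs [fit_air_coupling()] and [modifying_areas()] for every site x habitat
#' x quadrat x season x stratum cell (ground and underground handled
#' separately, as are burrows when present), integrating each fitted line
#' over that series' observed air-temperature range.
#'
#' @param dataset A `clean_dataset` or cleaned records tibble including air.
#' @param strata Strata to analyse.
#' @param min_pairs Minimum paired hours for a cell to be fitted.
#' @return A tibble of class `modifying_capacity` with one row per design
#'   cell: the fitted slope/intercept, their provenance, and the signed
#'   areas.
#' @export
modifying_capacity <- function(dataset, strata = c("ground", "underground"),
                               min_pairs = 10) {
  paired <- pair_with_air(dataset)
  paired <- dplyr::filter(paired, .data$stratum %in% strata)
  out <- paired |>
    dplyr::group_by(.data$site, .data$habitat, .data$quadrat_id,
                    .data$season, .data$stratum) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < min_pairs) return(tibble::tibble())
      fit <- fit_air_coupling(df)
      areas <- modifying_areas(fit$slope, fit$intercept,
                               fit$air_min, fit$air_max)
      dplyr::bind_cols(
        fit[c("slope", "intercept", "slope_se", "n_pairs", "n_days", "method")],
        areas[c("area_amplify", "area_buffer", "total_capacity")],
        fit[c("air_min", "air_max")]
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("modifying_capacity", class(out))
  out
}

#' Summarise modifying capacity by habitat, season and stratum
#'
#' @param capacity Output of [modifying_capacity()].
#' @return A tibble with mean slope, mean total capacity and the share of
#'   cells with net buffering (negative total) per habitat x season x
#'   stratum.
#' @export
capacity_summary <- function(capacity) {
  capacity |>
    dplyr::group_by(.data$habitat, .data$season, .data$stratum) |>
    dplyr::summarise(
      mean_slope = mean(.data$slope),
      mean_total = mean(.data$total_capacity),
      prop_buffering = mean(.data$total_capacity < 0),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}
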