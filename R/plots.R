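#' Plot a fitted thermal performance curve
#'
#' Points, fitted curve, and (optionally) the suitability band with Topt
#' marked.
#'
#' @param object A `tpc_fit`.
#' @param band Optional [suitability_band()] to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tpc_fit
#' @export
autoplot.tpc_fit <- function(object, band = NULL, ...) {
  rng <- range(object$points$body_temp_c)
  grid <- tibble::tibble(body_temp_c = seq(rng[1], rng[2], length.out = 200))
  grid$speed <- fit_curve(object)(grid$body_temp_c)
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(.data$body_temp_c, .data$mean_speed)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$speed),
                       linewidth = 0.8, colour = "#1b6ca8") +
    ggplot2::labs(x = "Body temperature (°C)",
                  y = expression(Righting ~ speed ~ (s^-1)),
                  title = sprintf("%s fit (n = %d)", object$model, object$n)) +
    ggplot2::theme_minimal()
  if (!is.null(band) && !is.na(band$lower) && !is.na(band$upper)) {
    p <- p +
      ggplot2::annotate("rect", xmin = band$lower, xmax = band$upper,
                        ymin = -Inf, ymax = Inf, alpha = 0.12,
                        fill = "#1b6ca8") +
      ggplot2::geom_vline(xintercept = band$topt, linetype = "dashed")
  }
  p
}

#' Median daily course of temperature by habitat and season
#'
#' Hourly medians (with interquartile ribbons) of the chosen strata across
#' quadrats and days, faceted by season -- the standard picture of how
#' invaded and native areas differ over the day.
#'
#' @param dataset A `clean_dataset` or cleaned records tibble.
#' @param strata Strata to show.
#' @return A ggplot.
#' @export
plot_diurnal_profiles <- function(dataset, strata = c("ground", "underground",
                                                      "air")) {
  rec <- dplyr::filter(dataset_records(dataset), .data$stratum %in% strata)
  prof <- rec |>
    dplyr::group_by(.data$stratum, .data$habitat, .data$season, .data$hour) |>
    dplyr::summarise(med = median(.data$temp_c),
                     lo = quantile(.data$temp_c, 0.25),
                     hi = quantile(.data$temp_c, 0.75), .groups = "drop")
  ggplot2::ggplot(prof, ggplot2::aes(.data$hour, .data$med,
                                     colour = .data$habitat,
                                     fill = .data$habitat)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(stratum ~ season) +
    ggplot2::labs(x = "Hour of day", y = "Operative temperature (°C)") +
    ggplot2::theme_minimal()
}

#' Daily course of the de habitat-quality index
#'
#' Mean (solid) and min/max (dashed) de per habitat over the day, faceted by
#' season. Values nearer zero mean better thermal habitat quality.
#'
#' @param de_rows Output of [hourly_de()].
#' @return A ggplot.
#' @export
plot_de_profiles <- function(de_rows) {
  prof <- de_daily_profile(de_rows)
  ggplot2::ggplot(prof, ggplot2::aes(.data$hour, .data$de_mean,
                                     colour = .data$habitat)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$de_min), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$de_max), linetype = "dashed") +
    ggplot2::facet_wrap(~season) +
    ggplot2::labs(x = "Hour of day", y = "de index (°C)") +
    ggplot2::theme_minimal()
}

#' Fitted coupling lines against the unity line
#'
#' One line per design cell over its observed air range, coloured by
#' habitat, with the 1:1 line in black: lines above unity amplify air
#' temperature, lines below buffer it.
#'
#' @param capacity Output of [modifying_capacity()].
#' @param stratum Stratum to show.
#' @return A ggplot.
#' @export
plot_capacity_lines <- function(capacity, stratum = "ground") {
  cap <- dplyr::filter(tibble::as_tibble(capacity), .data$stratum == !!stratum)
  segs <- cap |>
    dplyr::mutate(y_min = .data$intercept + .data$slope * .data$air_min,
                  y_max = .data$intercept + .data$slope * .data$air_max)
  rng <- range(c(segs$air_min, segs$air_max))
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$air_min, y = .data$y_min,
                                       xend = .data$air_max,
                                       yend = .data$y_max,
                                       colour = .data$habitat),
                          alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 1) +
    ggplot2::facet_wrap(~season) +
    ggplot2::coord_cartesian(xlim = rng, ylim = rng) +
    ggplot2::labs(x = "Air temperature (°C)",
                  y = "Microsite temperature (°C)") +
    ggplot2::theme_minimal()
}
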