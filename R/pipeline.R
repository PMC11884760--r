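#' Run the full thermal-landscape analysis
#'
#' End-to-end orchestration: clean the logger records, derive the thermal
#' suitability band (either by fitting a performance curve to righting
#' trials, or from an explicit band), compute the landscape metric suite and
#' the modifying capacity, and fit habitat-by-season contrasts for the
#' headline metrics. Deterministic for a given input and seed.
#'
#' @param records Raw joined logger records (see [read_otm_tables()] or
#'   [simulate_scenario()]`$records`).
#' @param events Service events tibble, or `NULL`.
#' @param trials Righting-trials tibble; required unless `band` is given.
#' @param band Optional explicit [suitability_band()]; skips curve fitting.
#' @param tpc_models_used Candidate curve names for the fit.
#' @param contrast_metrics Metric names to fit habitat contrasts for.
#' @param select_structures Run the REML/ML structure selection inside the
#'   contrasts (slower) or fit the full model directly.
#' @param cleaning Named list of cleaning parameters passed to
#'   [build_clean_dataset()].
#' @param seed Seed for the curve fit multi-start.
#' @return A list of class `thermoscape_run`: `clean`, `tpc` (fit set or
#'   `NULL`), `band`, `metrics`, `occupancy`, `capacity`,
#'   `capacity_summary`, `peak_hours`, `contrasts`.
#' @export
run_thermal_landscape <- function(records, events = NULL, trials = NULL,
                                  band = NULL,
                                  tpc_models_used = c("flinn", "flinn_exp",
                                                      "gaussian", "briere2"),
                                  contrast_metrics = c("daily_max",
                                                       "spatial_range",
                                                       "minutes_any_within"),
                                  select_structures = FALSE,
                                  cleaning = list(), seed = 1L) {
  if (is.null(band) && is.null(trials)) {
    abort("either `trials` (to fit a curve) or an explicit `band` is required",
          class = "thermoscape_config_error")
  }
  clean <- do.call(build_clean_dataset,
                   c(list(records = records, events = events), cleaning))

  tpc <- NULL
  if (is.null(band)) {
    points <- performance_points(trials)
    tpc <- fit_tpc_models(points, models = tpc_models_used, seed = seed)
    band <- tpc_traits(tpc$best)
    if (is.na(band$lower) || is.na(band$upper)) {
      abort(sprintf("suitability band not estimable from the fitted %s curve",
                    tpc$best$model),
            class = "thermoscape_fit_error")
    }
  }

  metrics <- landscape_metrics(clean, band)
  occupancy <- band_occupancy_profile(clean, band)
  capacity <- modifying_capacity(clean)
  peaks <- peak_heat_hour(clean, stratum = if ("air" %in% clean$records$stratum)
    "air" else "ground")

  contrasts <- purrr::map_dfr(
    intersect(contrast_metrics, unique(metrics$metric)),
    function(m) {
      rows <- dplyr::filter(metrics, .data$metric == m)
      ct <- tryCatch(
        habitat_contrasts(rows, select = select_structures),
        error = function(e) NULL
      )
      if (is.null(ct)) return(tibble::tibble())
      dplyr::mutate(tibble::as_tibble(ct), metric = m, .before = 1)
    }
  )

  structure(
    list(clean = clean, tpc = tpc, band = band, metrics = metrics,
         occupancy = occupancy, capacity = capacity,
         capacity_summary = capacity_summary(capacity),
         peak_hours = peaks, contrasts = contrasts),
    class = "thermoscape_run"
  )
}

#' @export
print.thermoscape_run <- function(x, ...) {
  cat("<thermoscape_run>\n")
  p <- x$clean$provenance
  cat(sprintf("  cleaned records: %d of %d retained\n",
              p[["retained"]], p[["raw"]]))
  if (!is.null(x$tpc)) {
    cat(sprintf("  TPC: %s, Topt %.2f degC, Pmax %.4f s^-1\n",
                x$tpc$best$model, x$band$topt, x$band$pmax))
  }
  cat(sprintf("  band: [%.2f, %.2f] degC at %.0f%% of peak\n",
              x$band$lower, x$band$upper, 100 * x$band$fraction))
  cat(sprintf("  %d metric rows, %d capacity cells, %d contrast rows\n",
              nrow(x$metrics), nrow(x$capacity), nrow(x$contrasts)))
  invisible(x)
}

#' Plain-text summary report of a pipeline run
#'
#' Per-habitat/season metric means, curve traits, capacity signs: a compact
#' human-readable digest whose numbers equal the corresponding table
#' aggregations.
#'
#' @param run A `thermoscape_run`.
#' @return Invisibly, a list of the summary tables printed.
#' @export
report_run <- function(run) {
  stopifnot(inherits(run, "thermoscape_run"))
  print(run)
  metric_means <- run$metrics |>
    dplyr::group_by(.data$metric, .data$habitat, .data$season) |>
    dplyr::summarise(mean_value = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
  cat("\nMetric means by habitat and season:\n")
  print(as.data.frame(metric_means), row.names = FALSE, digits = 4)
  cat("\nModifying capacity by habitat, season, stratum:\n")
  print(as.data.frame(run$capacity_summary), row.names = FALSE, digits = 4)
  if (nrow(run$contrasts) > 0) {
    cat("\nInvaded - native contrasts:\n")
    print(as.data.frame(run$contrasts[, c("metric", "season", "estimate",
                                          "conf_low", "conf_high", "p_value")]),
          row.names = FALSE, digits = 4)
  }
  invisible(list(metric_means = metric_means,
                 capacity = run$capacity_summary,
                 contrasts = run$contrasts))
}

#' Write the tables of a run to CSV files
#'
#' @param run A `thermoscape_run`.
#' @param dir Existing writable directory.
#' @return Invisibly, the paths written.
#' @export
write_run_csv <- function(run, dir) {
  stopifnot(inherits(run, "thermoscape_run"))
  if (!dir.exists(dir)) {
    abort(sprintf("directory does not exist: %s", dir),
          class = "thermoscape_io_error")
  }
  paths <- c(metrics = file.path(dir, "metrics.csv"),
             capacity = file.path(dir, "capacity.csv"),
             occupancy = file.path(dir, "occupancy.csv"))
  readr::write_csv(run$metrics, paths[["metrics"]])
  readr::write_csv(run$capacity, paths[["capacity"]])
  readr::write_csv(run$occupancy, paths[["occupancy"]])
  if (nrow(run$contrasts) > 0) {
    paths <- c(paths, contrasts = file.path(dir, "contrasts.csv"))
    readr::write_csv(run$contrasts, paths[["contrasts"]])
  }
  invisible(paths)
}
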