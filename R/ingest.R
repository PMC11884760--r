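#' Read logger, metadata and service-event tables
#'
#' Joins the hourly logger series with per-logger metadata and parses the
#' service-event log. Every logger id in the series must have a metadata row;
#' duplicated (logger, timestamp) pairs are an error because they indicate a
#' double read-out.
#'
#' @param logger_path CSV with `otm_id`, `timestamp` (ISO-8601, local clock),
#'   `temp_c`.
#' @param metadata_path CSV with `otm_id`, `site`, `habitat`, `quadrat_id`,
#'   `stratum`, `exposure`.
#' @param events_path CSV with `otm_id`, `timestamp`, `kind`
#'   (`deploy`/`reprogram`), or `NULL` for no events.
#' @return A list with `records` (joined tibble) and `events` (tibble).
#' @export
read_otm_tables <- function(logger_path, metadata_path, events_path = NULL) {
  loggers <- readr::read_csv(logger_path, show_col_types = FALSE,
                             col_types = readr::cols(otm_id = "c",
                                                     timestamp = "c",
                                                     temp_c = "d"))
  metadata <- readr::read_csv(metadata_path, show_col_types = FALSE,
                              col_types = readr::cols(.default = "c"))
  required <- c("otm_id", "site", "habitat", "quadrat_id", "stratum", "exposure")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0) {
    abort(sprintf("metadata is missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "thermoscape_data_error")
  }
  loggers$timestamp <- as.POSIXct(loggers$timestamp,
                                  format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  dup <- duplicated(loggers[c("otm_id", "timestamp")])
  if (any(dup)) {
    abort(sprintf("%d duplicated (otm_id, timestamp) logger rows", sum(dup)),
          class = "thermoscape_data_error")
  }
  unknown <- setdiff(unique(loggers$otm_id), metadata$otm_id)
  if (length(unknown) > 0) {
    abort(sprintf("logger ids without metadata: %s",
                  paste(unknown, collapse = ", ")),
          class = "thermoscape_data_error")
  }
  records <- dplyr::inner_join(loggers, metadata, by = "otm_id")
  events <- if (is.null(events_path)) {
    tibble::tibble(otm_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                   kind = character())
  } else {
    ev <- readr::read_csv(events_path, show_col_types = FALSE,
                          col_types = readr::cols(otm_id = "c", timestamp = "c",
                                                  kind = "c"))
    ev$timestamp <- as.POSIXct(ev$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC")
    ev
  }
  list(records = records, events = events)
}

#' Remove samples around logger service events
#'
#' Handling a logger during deployment or field reprogramming can disturb the
#' reading, so all samples of that logger within `window_h` hours of a
#' service event are dropped (closed interval on both sides: an event at
#' 12:00 with a 1 h window removes the 11:00, 12:00 and 13:00 samples).
#' Overlapping windows are unioned, never double-counted.
#'
#' @param records Logger records tibble (needs `otm_id`, `timestamp`).
#' @param events Service events tibble (`otm_id`, `timestamp`, `kind`).
#' @param window_h Half-width of the removal window, hours.
#' @return The records tibble with affected rows removed; the number removed
#'   is attached as attribute `n_removed`.
#' @export
strip_service_windows <- function(records, events, window_h = 1) {
  stopifnot(window_h >= 0)
  if (nrow(events) == 0) {
    return(structure(records, n_removed = 0L))
  }
  win <- events |>
    dplyr::transmute(.data$otm_id,
                     from = .data$timestamp - window_h * 3600,
                     to = .data$timestamp + window_h * 3600)
  hit <- dplyr::inner_join(
    dplyr::mutate(records, ..row = dplyr::row_number()),
    win, by = "otm_id", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$timestamp >= .data$from, .data$timestamp <= .data$to) |>
    dplyr::distinct(.data$..row)
  out <- if (nrow(hit) > 0) records[-hit$..row, ] else records
  structure(out, n_removed = nrow(hit))
}

#' Remove implausible values and isolated spikes
#'
#' A reproducible surrogate for manual visual screening of logger series:
#' removes samples outside plausibility bounds, and isolated spikes whose
#' absolute jump from *both* temporal neighbours (within the same logger
#' series) exceeds `spike_delta`. Only removes rows; never edits values.
#'
#' @param records Logger records tibble.
#' @param bounds Length-2 numeric, plausibility bounds in degC.
#' @param spike_delta Minimum absolute hour-to-hour jump (degC), on both
#'   sides, for a sample to count as an isolated spike.
#' @return Records with outliers removed; counts attached as attributes
#'   `n_bounds` and `n_spikes`.
#' @export
flag_outliers <- function(records, bounds = c(-10, 70), spike_delta = 20) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  out_of_bounds <- records$temp_c < bounds[1] | records$temp_c > bounds[2]
  records_ord <- records |>
    dplyr::mutate(..row = dplyr::row_number()) |>
    dplyr::arrange(.data$otm_id, .data$timestamp) |>
    dplyr::group_by(.data$otm_id) |>
    dplyr::mutate(
      ..spike = !is.na(dplyr::lag(.data$temp_c)) &
        !is.na(dplyr::lead(.data$temp_c)) &
        abs(.data$temp_c - dplyr::lag(.data$temp_c)) > spike_delta &
        abs(.data$temp_c - dplyr::lead(.data$temp_c)) > spike_delta
    ) |>
    dplyr::ungroup()
  spike <- logical(nrow(records))
  spike[records_ord$..row] <- records_ord$..spike
  drop <- out_of_bounds | spike
  structure(records[!drop, , drop = FALSE],
            n_bounds = sum(out_of_bounds),
            n_spikes = sum(spike & !out_of_bounds))
}

#' Restrict to the daytime window and study period
#'
#' Keeps samples whose hour lies in `[day_start, day_end]` (both boundaries
#' inclusive, so the default 07:00--19:00 yields 13 samples per full day) and
#' whose date lies within `[date_start, date_end]`.
#'
#' @param records Logger records tibble.
#' @param day_start,day_end Hour-of-day bounds (integers, inclusive).
#' @param date_start,date_end Optional date bounds (inclusive); `NULL` keeps
#'   all dates.
#' @return Filtered records with attributes `n_removed_daytime` and
#'   `n_removed_window`.
#' @export
restrict_daytime_window <- function(records, day_start = 7, day_end = 19,
                                    date_start = NULL, date_end = NULL) {
  stopifnot(day_start < day_end)
  hr <- hour_of(records$timestamp)
  keep_day <- hr >= day_start & hr <= day_end
  d <- date_of(records$timestamp)
  keep_window <- rep(TRUE, nrow(records))
  if (!is.null(date_start)) keep_window <- keep_window & d >= as.Date(date_start)
  if (!is.null(date_end)) keep_window <- keep_window & d <= as.Date(date_end)
  keep <- keep_day & keep_window
  if (!any(keep)) {
    warn("no records remain after daytime/window restriction")
  }
  structure(records[keep, , drop = FALSE],
            n_removed_daytime = sum(!keep_day),
            n_removed_window = sum(keep_day & !keep_window))
}

#' Build an analysis-ready cleaned dataset
#'
#' Composes the cleaning steps in fixed order -- service-window stripping,
#' outlier removal, daytime/period restriction -- then tags each sample with
#' its calendar date, hour and austral season. Cleaning only ever removes
#' rows, and the provenance counts reconcile exactly:
#' `raw = retained + sum(removals)`.
#'
#' @param records Raw joined logger records (see [read_otm_tables()]).
#' @param events Service events tibble (may be empty).
#' @param window_h Service-window half-width (hours).
#' @param bounds,spike_delta Outlier parameters, see [flag_outliers()].
#' @param day_start,day_end,date_start,date_end Daytime/period window, see
#'   [restrict_daytime_window()].
#' @return A list of class `clean_dataset`: `records` (tibble with added
#'   `date`, `hour`, `season`) and `provenance` (named counts).
#' @export
build_clean_dataset <- function(records, events = NULL, window_h = 1,
                                bounds = c(-10, 70), spike_delta = 20,
                                day_start = 7, day_end = 19,
                                date_start = NULL, date_end = NULL) {
  if (is.null(events)) {
    events <- tibble::tibble(otm_id = character(),
                             timestamp = as.POSIXct(character(), tz = "UTC"),
                             kind = character())
  }
  n_raw <- nrow(records)
  step1 <- strip_service_windows(records, events, window_h)
  step2 <- flag_outliers(step1, bounds, spike_delta)
  step3 <- restrict_daytime_window(step2, day_start, day_end,
                                   date_start, date_end)
  cleaned <- step3 |>
    tibble::as_tibble() |>
    dplyr::mutate(
      date = date_of(.data$timestamp),
      hour = hour_of(.data$timestamp),
      season = assign_season(.data$date)
    )
  provenance <- c(
    raw = n_raw,
    removed_service = attr(step1, "n_removed"),
    removed_bounds = attr(step2, "n_bounds"),
    removed_spikes = attr(step2, "n_spikes"),
    removed_daytime = attr(step3, "n_removed_daytime"),
    removed_window = attr(step3, "n_removed_window"),
    retained = nrow(cleaned)
  )
  stopifnot(provenance[["raw"]] ==
              provenance[["retained"]] + sum(provenance[2:6]))
  structure(list(records = cleaned, provenance = provenance),
            class = "clean_dataset")
}

#' @export
print.clean_dataset <- function(x, ...) {
  p <- x$provenance
  cat("<clean_dataset>\n")
  cat(sprintf("  retained %d of %d raw samples\n", p[["retained"]], p[["raw"]]))
  cat(sprintf("  removed: service %d, bounds %d, spikes %d, night %d, window %d\n",
              p[["removed_service"]], p[["removed_bounds"]], p[["removed_spikes"]],
              p[["removed_daytime"]], p[["removed_window"]]))
  invisible(x)
}

# accept either a clean_dataset or a plain records tibble
dataset_records <- function(dataset) {
  if (inherits(dataset, "clean_dataset")) return(dataset$records)
  rec <- tibble::as_tibble(dataset)
  if (!"date" %in% names(rec)) rec$date <- date_of(rec$timestamp)
  if (!"hour" %in% names(rec)) rec$hour <- hour_of(rec$timestamp)
  if (!"season" %in% names(rec)) rec$season <- assign_season(rec$date)
  rec
}
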