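#' Per-individual performance points from righting trials
#'
#' Failed repetitions (missing righting time) are dropped; each successful
#' repetition contributes a speed `1 / time`; speeds (not times) are averaged
#' per individual x treatment (the mean of reciprocals, not the reciprocal of
#' the mean). The temperature paired with each point is the mean measured
#' body temperature over the contributing repetitions, falling back to the
#' treatment temperature when no body temperature was recorded
#' (`temp_source` says which).
#'
#' @param trials Righting-trials tibble (see [generate_righting_trials()]).
#' @return A tibble with `individual_id`, `site`, `season`, `sex`,
#'   `treatment_c`, `body_temp_c`, `mean_speed`, `n_reps`, `temp_source`.
#' @examples
#' trials <- tibble::tibble(
#'   individual_id = "i1", site = "s", season = "spring", sex = "f",
#'   treatment_c = 25, body_temp_c = c(24.8, 25.1), rep = 1:2,
#'   righting_time_s = c(5, 10)
#' )
#' performance_points(trials)$mean_speed # (1/5 + 1/10) / 2 = 0.15
#' @export
performance_points <- function(trials) {
  ok <- trials |>
    dplyr::filter(!is.na(.data$righting_time_s))
  if (any(ok$righting_time_s <= 0)) {
    abort("righting_time_s must be > 0", class = "thermoscape_data_error")
  }
  ok |>
    dplyr::group_by(.data$individual_id, .data$site, .data$season, .data$sex,
                    .data$treatment_c) |>
    dplyr::summarise(
      mean_speed = mean(1 / .data$righting_time_s),
      body_mean = mean(.data$body_temp_c[!is.na(.data$body_temp_c)]),
      n_reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      temp_source = ifelse(is.nan(.data$body_mean), "treatment", "body"),
      body_temp_c = ifelse(is.nan(.data$body_mean), .data$treatment_c,
                           .data$body_mean)
    ) |>
    dplyr::select("individual_id", "site", "season", "sex", "treatment_c",
                  "body_temp_c", "mean_speed", "n_reps", "temp_source")
}

#' Small-sample corrected AIC for a least-squares fit
#'
#' Uses the Gaussian least-squares form
#' `AICc = n log(RSS/n) + 2k + 2k(k+1)/(n-k-1)`, where `k` must count the
#' residual-variance parameter alongside the curve parameters (so a
#' three-parameter curve has `k = 4`).
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Number of estimated parameters including the error variance.
#' @return The AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) {
    abort(sprintf("AICc needs n > k + 1 (n = %d, k = %d)", n, k),
          class = "thermoscape_config_error")
  }
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one thermal-performance-curve model by bounded least squares
#'
#' Minimises the residual sum of squares of `mean_speed` against the model
#' curve in `body_temp_c` with the Levenberg--Marquardt algorithm under box
#' constraints, from a seeded multi-start grid (curve families with a
#' quadratic or exponent term have local minima). The best converged start
#' wins.
#'
#' @param points Performance points (needs `body_temp_c`, `mean_speed`).
#' @param model Registered model name (see [tpc_models()]).
#' @param n_starts Number of random starts.
#' @param seed Seed for the start grid.
#' @return An object of class `tpc_fit`: model name, named `params`, `n`,
#'   `rss`, `aicc`, `converged`, and the fitted points.
#' @export
fit_tpc <- function(points, model = "flinn", n_starts = 20, seed = 1L) {
  spec <- tpc_models(model)[[1]]
  temp <- points$body_temp_c
  speed <- points$mean_speed
  keep <- is.finite(temp) & is.finite(speed)
  temp <- temp[keep]; speed <- speed[keep]
  n <- length(temp)
  k_curve <- length(spec$params)
  if (n < k_curve + 2 || dplyr::n_distinct(round(temp, 6)) < 3) {
    abort(sprintf("fit_tpc('%s') needs at least %d points over >= 3 distinct temperatures (got %d)",
                  model, k_curve + 2, n),
          class = "thermoscape_data_error")
  }
  starts <- withr::with_seed(seed, spec$start_fn(temp, speed, n_starts))
  resid_fn <- function(par) {
    pred <- spec$fn(as.list(setNames(par, spec$params)), temp)
    r <- speed - pred
    r[!is.finite(r)] <- 1e3
    r
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- pmin(pmax(starts[i, spec$params], spec$lower), spec$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = spec$lower, upper = spec$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = setNames(as.numeric(fit$par), spec$params), rss = rss)
    }
  }
  converged <- !is.null(best)
  if (!converged) {
    best <- list(par = setNames(rep(NA_real_, k_curve), spec$params),
                 rss = NA_real_)
  }
  structure(
    list(model = model,
         params = best$par,
         n = n,
         rss = best$rss,
         aicc = if (converged) aicc(best$rss, n, k_curve + 1) else NA_real_,
         converged = converged,
         points = tibble::tibble(body_temp_c = temp, mean_speed = speed)),
    class = "tpc_fit"
  )
}

#' Fit several candidate models and select by AICc
#'
#' @param points Performance points.
#' @param models Character vector of registry names.
#' @inheritParams fit_tpc
#' @return A list of class `tpc_fit_set`: `fits` (named list of `tpc_fit`),
#'   `best` (the selected fit), `aicc_table` (tibble).
#' @export
fit_tpc_models <- function(points, models = c("flinn", "flinn_exp",
                                              "gaussian", "briere2", "weibull"),
                           n_starts = 20, seed = 1L) {
  fits <- purrr::map(setNames(models, models),
                     function(m) fit_tpc(points, m, n_starts, seed))
  best <- select_tpc(fits)
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$model, n_params = length(f$params), n = f$n,
                   rss = f$rss, aicc = f$aicc, converged = f$converged)
  }) |>
    dplyr::arrange(.data$aicc)
  structure(list(fits = fits, best = best, aicc_table = tab),
            class = "tpc_fit_set")
}

#' Select the best fit by AICc
#'
#' Lowest AICc among converged fits; ties broken by fewer parameters, then by
#' model name.
#'
#' @param fits A list of `tpc_fit` objects.
#' @return The selected `tpc_fit`.
#' @export
select_tpc <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) {
    abort("no candidate model converged", class = "thermoscape_fit_error")
  }
  ord <- order(vapply(fits, function(f) f$aicc, numeric(1)),
               vapply(fits, function(f) length(f$params), numeric(1)),
               vapply(fits, function(f) f$model, character(1)))
  fits[[ord[1]]]
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("<tpc_fit> %s (%s), n = %d\n", x$model,
              if (x$converged) "converged" else "failed", x$n))
  if (x$converged) {
    cat("  params:", paste(sprintf("%s = %.5g", names(x$params), x$params),
                           collapse = ", "), "\n")
    cat(sprintf("  RSS = %.5g, AICc = %.2f\n", x$rss, x$aicc))
  }
  invisible(x)
}

#' @export
print.tpc_fit_set <- function(x, ...) {
  cat("<tpc_fit_set> selected:", x$best$model, "\n")
  print(as.data.frame(x$aicc_table), row.names = FALSE)
  invisible(x)
}

#' @method tidy tpc_fit
#' @export
tidy.tpc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = as.numeric(x$params))
}

#' @method glance tpc_fit
#' @export
glance.tpc_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n = x$n, rss = x$rss, AICc = x$aicc,
                 converged = x$converged)
}

# curve evaluator bound to a fit
fit_curve <- function(fit) {
  spec <- tpc_models(fit$model)[[1]]
  function(temp) spec$fn(as.list(fit$params), temp)
}
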