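#' Design for synthetic righting-response trials
#'
#' Describes a laboratory righting-trial experiment: individuals tested at a
#' series of treatment temperatures, several repetitions per temperature,
#' with righting speed drawn from a known thermal performance curve plus
#' observation noise, and failures (no successful righting) at temperature
#' extremes.
#'
#' The default generating curve is the quadratic-denominator Flinn-type form
#' `speed = 1 / (1 + a + b*T + c*T^2)` with `a = 76.79`, `b = -4.45`,
#' `c = 0.07`, whose analytic optimum lies near 31.8 degC.
#'
#' @param true_params Named list: `model` (a registered curve name, see
#'   [tpc_models()]) and its parameters.
#' @param n_individuals Number of individuals.
#' @param treatment_temps Strictly increasing treatment temperatures (degC).
#' @param reps_per_temp Repetitions per individual x temperature.
#' @param obs_sigma Gaussian observation noise on speed (s^-1), truncated to
#'   keep speeds positive.
#' @param body_temp_sigma SD (degC) of measured body temperature around the
#'   treatment temperature (imperfect equilibration).
#' @param failure_rule Function of temperature returning the probability that
#'   a repetition yields no successful righting. The default concentrates
#'   failures at the cold and hot extremes.
#' @param sites,seasons,sexes Label pools individuals are assigned to
#'   (round-robin), so covariate screens have something to test.
#' @param seed Integer seed.
#' @return A list of class `righting_design`.
#' @export
righting_design <- function(true_params = list(model = "flinn",
                                               a = 76.79, b = -4.45, c = 0.07),
                            n_individuals = 66,
                            treatment_temps = seq(10, 35, by = 5),
                            reps_per_temp = 3,
                            obs_sigma = 0.01,
                            body_temp_sigma = 0.7,
                            failure_rule = default_failure_rule,
                            sites = c("siteA", "siteB"),
                            seasons = c("spring", "autumn"),
                            sexes = c("female", "male"),
                            seed = 1L) {
  if (obs_sigma < 0) {
    abort("obs_sigma must be >= 0", class = "thermoscape_config_error")
  }
  if (any(diff(treatment_temps) <= 0)) {
    abort("treatment_temps must be strictly increasing",
          class = "thermoscape_config_error")
  }
  stopifnot(is.function(failure_rule), is.list(true_params),
            !is.null(true_params$model))
  structure(
    list(true_params = true_params,
         n_individuals = as.integer(n_individuals),
         treatment_temps = treatment_temps,
         reps_per_temp = as.integer(reps_per_temp),
         obs_sigma = obs_sigma,
         body_temp_sigma = body_temp_sigma,
         failure_rule = failure_rule,
         sites = sites, seasons = seasons, sexes = sexes,
         seed = as.integer(seed)),
    class = "righting_design"
  )
}

#' Default failure probability for righting repetitions
#'
#' Failures are rare at intermediate temperatures and concentrate at the cold
#' end (torpid animals) with a smaller hot-end component.
#'
#' @param temp_c Temperature (degC).
#' @return Failure probability in [0, 1].
#' @export
default_failure_rule <- function(temp_c) {
  pmin(1, 0.6 * stats::plogis((12 - temp_c) / 2) +
         0.2 * stats::plogis((temp_c - 37) / 1.5))
}

# evaluate the design's generating curve
design_curve <- function(design, temp) {
  p <- design$true_params
  tpc_eval(p$model, p[setdiff(names(p), "model")], temp)
}

#' Generate synthetic righting-response trials
#'
#' For each individual x treatment x repetition, the measured body
#' temperature is the treatment temperature plus equilibration noise, speed
#' is the generating curve at that body temperature plus truncated Gaussian
#' noise, and the recorded outcome is the successful righting time
#' `1 / speed` -- or a failure (missing time) with probability given by the
#' design's failure rule.
#'
#' @param design A [righting_design()].
#' @return A tibble with columns `individual_id`, `site`, `season`, `sex`,
#'   `treatment_c`, `body_temp_c`, `rep`, `righting_time_s` (`NA` = failure).
#' @export
generate_righting_trials <- function(design) {
  stopifnot(inherits(design, "righting_design"))
  withr::with_seed(design$seed, {
    ind <- tibble::tibble(
      individual_id = sprintf("ind%03d", seq_len(design$n_individuals)),
      site = rep_len(design$sites, design$n_individuals),
      season = rep_len(rep(design$seasons,
                           each = max(1, ceiling(design$n_individuals / length(design$seasons)))),
                       design$n_individuals),
      sex = rep_len(design$sexes, design$n_individuals)
    )
    grid <- tidyr::expand_grid(
      ind,
      treatment_c = design$treatment_temps,
      rep = seq_len(design$reps_per_temp)
    )
    n <- nrow(grid)
    body <- grid$treatment_c + rnorm(n, 0, design$body_temp_sigma)
    true_speed <- design_curve(design, body)
    speed <- true_speed + rnorm(n, 0, design$obs_sigma)
    # truncate at > 0 by redrawing the noise
    for (i in seq_len(50)) {
      bad <- which(speed <= 0)
      if (length(bad) == 0) break
      speed[bad] <- true_speed[bad] + rnorm(length(bad), 0, design$obs_sigma)
    }
    speed <- pmax(speed, 1e-6)
    failed <- runif(n) < design$failure_rule(grid$treatment_c)
    dplyr::mutate(
      grid,
      body_temp_c = body,
      righting_time_s = ifelse(failed, NA_real_, 1 / speed)
    ) |>
      dplyr::select("individual_id", "site", "season", "sex", "treatment_c",
                    "body_temp_c", "rep", "righting_time_s")
  })
}

#' Read a righting-trials CSV
#'
#' @param path CSV with columns `individual_id`, `site`, `season`, `sex`,
#'   `treatment_c`, `body_temp_c`, `rep`, `righting_time_s` (empty = failure).
#' @return A validated trials tibble.
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              individual_id = "c", site = "c", season = "c",
                              sex = "c", treatment_c = "d", body_temp_c = "d",
                              rep = "i", righting_time_s = "d"
                            ))
  bad <- which(!is.na(trials$righting_time_s) & trials$righting_time_s <= 0)
  if (length(bad) > 0) {
    abort(sprintf("righting_time_s must be > 0 when present (%d bad rows)",
                  length(bad)),
          class = "thermoscape_data_error")
  }
  trials
}
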