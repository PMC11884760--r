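#' Choose a random-effect structure by REML AIC
#'
#' Fits the same fixed-effect structure under each candidate random-effect
#' structure with REML and keeps the lowest-AIC candidate, mirroring the
#' usual two-stage mixed-model protocol (random structure under REML first,
#' fixed structure under ML second). Candidates whose grouping factors have
#' fewer than two levels in the data are dropped with a warning; singular
#' fits are excluded, and if every candidate is singular (or none fits) the
#' result falls back to no random effects, flagged.
#'
#' @param data A data frame.
#' @param response Response column name.
#' @param fixed Fixed-effects right-hand side, e.g. `"habitat * season"`.
#' @param random_candidates Character vector of random-effect terms, e.g.
#'   `c("(1|site) + (1|quadrat_id)", "(1|site)")`.
#' @return A list: `random` (chosen term string, or `NULL` for the fallback),
#'   `fallback` (logical), `aic_table` (tibble).
#' @export
select_random_structure <- function(data, response, fixed,
                                    random_candidates) {
  usable <- purrr::keep(random_candidates, function(rc) {
    vars <- all.vars(stats::as.formula(paste("~", rc)))
    ok <- vapply(vars, function(v) dplyr::n_distinct(data[[v]]) >= 2, logical(1))
    if (!all(ok)) {
      warn(sprintf("dropping random candidate '%s': grouping factor with < 2 levels", rc))
    }
    all(ok)
  })
  empty <- tibble::tibble(random = character(), aic = numeric(),
                          singular = logical())
  if (length(usable) == 0) {
    return(list(random = NULL, fallback = TRUE, aic_table = empty))
  }
  rows <- purrr::map_dfr(usable, function(rc) {
    f <- stats::as.formula(paste(response, "~", fixed, "+", rc))
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(f, data = data, REML = TRUE)),
      error = function(e) NULL
    )
    tibble::tibble(
      random = rc,
      aic = if (is.null(fit)) NA_real_ else AIC(fit),
      singular = if (is.null(fit)) NA else lme4::isSingular(fit, tol = 1e-5)
    )
  })
  ok <- rows[!is.na(rows$aic) & !rows$singular, ]
  if (nrow(ok) == 0) {
    return(list(random = NULL, fallback = TRUE, aic_table = rows))
  }
  list(random = ok$random[which.min(ok$aic)], fallback = FALSE,
       aic_table = rows)
}

#' Choose a fixed-effect structure by ML AIC and refit with REML
#'
#' Fits every candidate fixed structure under maximum likelihood with the
#' given (already selected) random structure, keeps the strictly lowest AIC
#' (ties go to the earlier, simpler candidate -- list candidates simplest
#' first), and refits the winner with REML for reporting.
#'
#' @inheritParams select_random_structure
#' @param fixed_candidates Character vector of fixed-effect right-hand
#'   sides, ordered simplest to most complex.
#' @param random Random-effect term string, or `NULL` for ordinary least
#'   squares.
#' @return A list: `fixed` (chosen RHS), `model` (final REML or `lm` fit),
#'   `aic_table` (tibble).
#' @export
select_fixed_structure <- function(data, response, fixed_candidates, random) {
  fit_one <- function(rhs, reml) {
    if (is.null(random)) {
      lm(stats::as.formula(paste(response, "~", rhs)), data = data)
    } else {
      suppressMessages(lmerTest::lmer(
        stats::as.formula(paste(response, "~", rhs, "+", random)),
        data = data, REML = reml
      ))
    }
  }
  rows <- purrr::map_dfr(fixed_candidates, function(rhs) {
    fit <- tryCatch(fit_one(rhs, reml = FALSE), error = function(e) NULL)
    tibble::tibble(fixed = rhs,
                   aic = if (is.null(fit)) NA_real_ else AIC(fit))
  })
  ok <- rows[!is.na(rows$aic), ]
  if (nrow(ok) == 0) {
    abort("no fixed-effect candidate could be fitted",
          class = "thermoscape_fit_error")
  }
  best <- ok$fixed[which.min(ok$aic)] # which.min takes the first = simplest tie
  list(fixed = best, model = fit_one(best, reml = TRUE), aic_table = rows)
}

#' Habitat-by-season contrasts for a thermal-landscape metric
#'
#' Fits the metric against habitat and season with site and quadrat as
#' random intercepts, optionally running the two-stage structure selection
#' first, and reports the invaded-minus-native contrast per season with a
#' 95% confidence interval and a Satterthwaite-approximation p-value. When
#' model selection drops the habitat term, the contrast is still reported
#' from a refit that retains it, with `term_selected = FALSE`.
#'
#' @param metric_rows Metric rows (needs `habitat`, `season`, `site`,
#'   `quadrat_id` and the value column); typically one metric at a time.
#' @param value_col Name of the value column.
#' @param select Run the REML/ML structure selection (default) or fit
#'   `value ~ habitat * season` (or `~ habitat` for one season) directly.
#' @return A tibble of class `habitat_contrasts`: one row per season with
#'   `estimate` (invaded - native), `conf_low`, `conf_high`, `p_value`,
#'   `model_aic`, `n`, `term_selected`, plus the fit as attribute `model`.
#' @export
habitat_contrasts <- function(metric_rows, value_col = "value",
                              select = TRUE) {
  data <- tibble::as_tibble(metric_rows)
  if (dplyr::n_distinct(data$habitat) < 2) {
    abort("habitat contrasts need both habitats present",
          class = "thermoscape_data_error")
  }
  data$habitat <- factor(as.character(data$habitat), levels = habitat_levels())
  data$season <- droplevels(factor(as.character(data$season),
                                   levels = season_levels()))
  data$.value <- data[[value_col]]
  multi_season <- dplyr::n_distinct(data$season) > 1

  random_candidates <- c("(1|site) + (1|quadrat_id)", "(1|site)",
                         "(1|quadrat_id)")
  full_fixed <- if (multi_season) "habitat * season" else "habitat"
  fixed_candidates <- if (multi_season) {
    c("1", "season", "habitat", "habitat + season", "habitat * season")
  } else {
    c("1", "habitat")
  }

  if (select) {
    rand <- select_random_structure(data, ".value", full_fixed,
                                    random_candidates)
    fx <- select_fixed_structure(data, ".value", fixed_candidates,
                                 rand$random)
    chosen_fixed <- fx$fixed
    term_selected <- grepl("habitat", chosen_fixed)
    contrast_rhs <- if (term_selected) chosen_fixed else full_fixed
    model <- if (term_selected) {
      fx$model
    } else {
      select_fixed_structure(data, ".value", contrast_rhs, rand$random)$model
    }
    random_used <- rand$random
  } else {
    term_selected <- TRUE
    random_used <- random_candidates[1]
    model <- tryCatch(
      suppressMessages(lmerTest::lmer(
        stats::as.formula(paste(".value ~", full_fixed, "+", random_used)),
        data = data, REML = TRUE
      )),
      error = function(e) lm(stats::as.formula(paste(".value ~", full_fixed)),
                             data = data)
    )
  }

  emm <- if (multi_season) {
    emmeans::emmeans(model, ~ habitat | season, data = data,
                     lmer.df = "satterthwaite")
  } else {
    emmeans::emmeans(model, ~ habitat, data = data,
                     lmer.df = "satterthwaite")
  }
  ct <- summary(emmeans::contrast(emm, method = "revpairwise"),
                infer = c(TRUE, TRUE))
  out <- tibble::tibble(
    season = if (multi_season) as.character(ct$season)
             else as.character(unique(data$season)),
    contrast = as.character(ct$contrast),
    estimate = ct$estimate,
    conf_low = ct$lower.CL,
    conf_high = ct$upper.CL,
    p_value = ct$p.value,
    model_aic = AIC(model),
    n = nrow(data),
    term_selected = term_selected
  )
  attr(out, "model") <- model
  attr(out, "random") <- random_used
  class(out) <- c("habitat_contrasts", class(out))
  out
}

#' Screen righting speed for site, season and sex effects
#'
#' Fits mean righting speed against a polynomial in body temperature plus
#' the candidate grouping terms (site, season, sex), with a random intercept
#' per individual, and selects the fixed structure by ML AIC (random
#' structure kept as the individual intercept throughout, per the standard
#' protocol). The verdict is `"pool"` when no grouping term survives --
#' justifying a single pooled thermal performance curve -- and `"split"`
#' otherwise, listing the surviving terms.
#'
#' @param points Performance points (see [performance_points()]).
#' @param screen_terms Candidate grouping terms to test.
#' @param poly_degree Degree of the body-temperature polynomial.
#' @return A list: `verdict` (`"pool"`/`"split"`), `terms` (surviving
#'   grouping terms), `fixed` (chosen RHS), `aic_table`.
#' @export
righting_screen <- function(points, screen_terms = c("site", "season", "sex"),
                            poly_degree = 2) {
  data <- tibble::as_tibble(points)
  usable <- purrr::keep(screen_terms,
                        function(v) v %in% names(data) &&
                          dplyr::n_distinct(data[[v]]) >= 2)
  base <- sprintf("poly(body_temp_c, %d)", poly_degree)
  subsets <- unlist(purrr::map(0:length(usable), function(k) {
    if (k == 0) return(list(character(0)))
    utils::combn(usable, k, simplify = FALSE)
  }), recursive = FALSE)
  candidates <- vapply(subsets, function(s) paste(c(base, s), collapse = " + "),
                       character(1))
  random <- if (dplyr::n_distinct(data$individual_id) >= 2) {
    "(1|individual_id)"
  } else {
    NULL
  }
  fx <- select_fixed_structure(data, "mean_speed", candidates, random)
  surviving <- usable[vapply(usable, function(v) grepl(v, fx$fixed, fixed = TRUE),
                             logical(1))]
  list(
    verdict = if (length(surviving) == 0) "pool" else "split",
    terms = surviving,
    fixed = fx$fixed,
    aic_table = fx$aic_table
  )
}
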