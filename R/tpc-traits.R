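#' Construct an explicit thermal suitability band
#'
#' A `suitability_band` is the temperature interval over which performance is
#' at least `fraction` of the curve's peak (the default 0.8 gives the B80
#' breadth). Either bound may be `NA` when it could not be estimated from the
#' available temperature range.
#'
#' @param lower,upper Band bounds (degC); `lower < upper` when both present.
#' @param fraction Fraction of peak performance defining the band.
#' @param topt,pmax Optional curve traits to carry along.
#' @return An object of class `suitability_band`.
#' @export
suitability_band <- function(lower, upper, fraction = 0.8,
                             topt = NA_real_, pmax = NA_real_) {
  if (!is.na(lower) && !is.na(upper) && lower >= upper) {
    abort("band lower bound must be below the upper bound",
          class = "thermoscape_config_error")
  }
  structure(list(lower = lower, upper = upper, fraction = fraction,
                 topt = topt, pmax = pmax),
            class = "suitability_band")
}

#' @export
print.suitability_band <- function(x, ...) {
  cat(sprintf("<suitability_band> [%s, %s] degC at %.0f%% of peak",
              format(round(x$lower, 2)), format(round(x$upper, 2)),
              100 * x$fraction))
  if (!is.na(x$topt)) {
    cat(sprintf(" (Topt %.2f degC, Pmax %.4g)", x$topt, x$pmax))
  }
  cat("\n")
  invisible(x)
}

#' Extract Topt, Pmax and the suitability band from a fitted curve
#'
#' The optimal temperature is found by bounded scalar maximisation over the
#' observed temperature support widened by `margin` on each side; `Pmax` is
#' the curve value there. Each band bound is the root of
#' `curve(T) - fraction * Pmax` on its side of `Topt`; when the curve never
#' drops to the threshold within the search interval the bound is reported as
#' `NA` (not estimable from the tested temperature range). The fitted curve
#' must be unimodal over the interval.
#'
#' @param fit A converged `tpc_fit`.
#' @param fraction Fraction of peak performance (default 0.8, i.e. B80).
#' @param margin Extrapolation margin (degC) beyond the observed temperatures.
#' @return A `suitability_band` carrying `topt` and `pmax`.
#' @export
tpc_traits <- function(fit, fraction = 0.8, margin = 5) {
  stopifnot(inherits(fit, "tpc_fit"))
  if (!fit$converged) {
    abort("cannot extract traits from a non-converged fit",
          class = "thermoscape_fit_error")
  }
  stopifnot(fraction > 0, fraction <= 1)
  f <- fit_curve(fit)
  lo <- min(fit$points$body_temp_c) - margin
  hi <- max(fit$points$body_temp_c) + margin

  grid <- seq(lo, hi, length.out = 2001)
  v <- f(grid)
  if (any(!is.finite(v))) {
    # restrict to the finite stretch around the maximum
    ok <- is.finite(v)
    lo <- min(grid[ok]); hi <- max(grid[ok])
    grid <- seq(lo, hi, length.out = 2001)
    v <- f(grid)
  }
  check_unimodal(v, fit$model)

  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-9)
  topt <- opt$maximum
  pmax_val <- opt$objective
  target <- fraction * pmax_val

  if (fraction == 1) {
    return(structure(list(lower = topt, upper = topt, fraction = fraction,
                          topt = topt, pmax = pmax_val),
                     class = "suitability_band"))
  }
  g <- function(t) f(t) - target
  lower <- if (g(lo) < 0) uniroot(g, c(lo, topt), tol = 1e-9)$root else NA_real_
  upper <- if (g(hi) < 0) uniroot(g, c(topt, hi), tol = 1e-9)$root else NA_real_
  suitability_band(lower, upper, fraction, topt = topt, pmax = pmax_val)
}

# error if the gridded curve has more than one rise-fall alternation
check_unimodal <- function(v, model) {
  d <- diff(v)
  eps <- 1e-10 * max(abs(v), 1)
  s <- sign(d)[abs(d) > eps]
  if (length(s) == 0) return(invisible(TRUE))
  runs <- rle(s)$values
  bad <- length(runs) > 2 || (length(runs) == 2 && !identical(runs, c(1, -1)))
  if (length(runs) == 1 && runs[1] == -1) bad <- FALSE # monotone decline
  if (bad) {
    abort(sprintf("fitted '%s' curve is not unimodal over the search interval",
                  model),
          class = "thermoscape_fit_error")
  }
  invisible(TRUE)
}

#' @method tidy suitability_band
#' @export
tidy.suitability_band <- function(x, ...) {
  tibble::tibble(lower_c = x$lower, upper_c = x$upper, fraction = x$fraction,
                 topt_c = x$topt, pmax = x$pmax)
}
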