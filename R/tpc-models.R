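#' Registry of candidate thermal-performance-curve models
#'
#' All candidates have at most four free parameters. Two Flinn-type forms are
#' shipped: `flinn`, the quadratic-denominator form
#' `1 / (1 + a + b*T + c*T^2)` (symmetric about its vertex), and
#' `flinn_exp`, the logistic-exponent form `1 / (1 + exp(a + b*T + c*T^2))`
#' (asymmetric). `gaussian` is the symmetric bell
#' `pmax * exp(-0.5 ((T - topt)/sigma)^2)`; `briere2` is
#' `a * T * (T - tmin) * (tmax - T)^(1/b)` clamped to zero outside
#' `(tmin, tmax)`; `weibull` is the four-parameter Weibull-shaped curve with
#' its mode at `topt` and height `a`.
#'
#' @param names Optional character vector to subset the registry.
#' @return A named list of model specs (name, parameter names, bounds,
#'   evaluation function, start generator).
#' @export
tpc_models <- function(names = NULL) {
  registry <- list(
    flinn = list(
      name = "flinn",
      params = c("a", "b", "c"),
      lower = c(a = -1, b = -50, c = 1e-6),
      upper = c(a = 5000, b = 0, c = 5),
      fn = function(p, temp) {
        den <- 1 + p[["a"]] + p[["b"]] * temp + p[["c"]] * temp^2
        ifelse(den > 0, 1 / den, NA_real_)
      },
      start_fn = start_from_vertex(function(t0, p0, c) {
        c(a = 1 / p0 - 1 + c * t0^2, b = -2 * c * t0, c = c)
      }, c_range = c(0.01, 0.3))
    ),
    flinn_exp = list(
      name = "flinn_exp",
      params = c("a", "b", "c"),
      lower = c(a = -500, b = -100, c = 1e-6),
      upper = c(a = 500, b = 0, c = 10),
      fn = function(p, temp) {
        1 / (1 + exp(pmin(700, p[["a"]] + p[["b"]] * temp + p[["c"]] * temp^2)))
      },
      start_fn = start_from_vertex(function(t0, p0, c) {
        q0 <- log(pmax(1e-8, 1 / p0 - 1))
        c(a = q0 + c * t0^2, b = -2 * c * t0, c = c)
      }, c_range = c(0.005, 0.2))
    ),
    gaussian = list(
      name = "gaussian",
      params = c("pmax", "topt", "sigma"),
      lower = c(pmax = 1e-8, topt = -20, sigma = 0.1),
      upper = c(pmax = 100, topt = 80, sigma = 100),
      fn = function(p, temp) {
        p[["pmax"]] * exp(-0.5 * ((temp - p[["topt"]]) / p[["sigma"]])^2)
      },
      start_fn = function(temp, speed, n) {
        t0 <- temp[which.max(speed)]
        cbind(pmax = max(speed) * runif(n, 0.8, 1.2),
              topt = t0 + runif(n, -4, 4),
              sigma = runif(n, 2, 15))
      }
    ),
    briere2 = list(
      name = "briere2",
      params = c("a", "tmin", "tmax", "b"),
      lower = c(a = 1e-10, tmin = -30, tmax = 25, b = 0.5),
      upper = c(a = 1, tmin = 20, tmax = 120, b = 10),
      fn = function(p, temp) {
        core <- p[["a"]] * temp * (temp - p[["tmin"]]) *
          pmax(0, p[["tmax"]] - temp)^(1 / p[["b"]])
        ifelse(temp > p[["tmin"]] & temp < p[["tmax"]] & core > 0, core, 0)
      },
      start_fn = function(temp, speed, n) {
        cbind(a = max(speed) / max(temp)^2 * runif(n, 0.05, 2),
              tmin = runif(n, -10, min(temp) - 1),
              tmax = runif(n, max(temp) + 1, max(temp) + 30),
              b = runif(n, 1, 6))
      }
    ),
    weibull = list(
      name = "weibull",
      params = c("a", "topt", "b", "c"),
      lower = c(a = 1e-8, topt = -20, b = 0.5, c = 1.2),
      upper = c(a = 100, topt = 80, b = 200, c = 30),
      fn = function(p, temp) {
        cc <- p[["c"]]
        k <- ((cc - 1) / cc)^(1 / cc)
        z <- (temp - p[["topt"]]) / p[["b"]] + k
        val <- p[["a"]] * ((cc - 1) / cc)^((1 - cc) / cc) *
          ifelse(z > 0, z^(cc - 1) * exp(-z^cc + (cc - 1) / cc), 0)
        ifelse(is.finite(val) & z > 0, val, 0)
      },
      start_fn = function(temp, speed, n) {
        t0 <- temp[which.max(speed)]
        cbind(a = max(speed) * runif(n, 0.8, 1.2),
              topt = t0 + runif(n, -4, 4),
              b = runif(n, 5, 40),
              c = runif(n, 1.5, 6))
      }
    )
  )
  if (is.null(names)) return(registry)
  unknown <- setdiff(names, base::names(registry))
  if (length(unknown) > 0) {
    abort(sprintf("unknown TPC model(s): %s", paste(unknown, collapse = ", ")),
          class = "thermoscape_config_error")
  }
  registry[names]
}

# start generator for the two Flinn-type forms: sample a curvature and a
# vertex (position, height) near the empirical maximum, then map to (a, b, c)
start_from_vertex <- function(map, c_range) {
  function(temp, speed, n) {
    t0 <- temp[which.max(speed)]
    p0 <- max(speed)
    out <- t(vapply(seq_len(n), function(i) {
      map(t0 + runif(1, -4, 4), p0 * runif(1, 0.7, 1.3),
          runif(1, c_range[1], c_range[2]))
    }, numeric(3)))
    colnames(out) <- c("a", "b", "c")
    out
  }
}

#' Evaluate a registered thermal-performance curve
#'
#' @param model Registered model name (see [tpc_models()]).
#' @param params Named list or vector of the model's parameters.
#' @param temp Temperatures (degC).
#' @return Predicted performance (righting speed, s^-1).
#' @export
tpc_eval <- function(model, params, temp) {
  spec <- tpc_models(model)[[1]]
  p <- as.list(params)
  missing <- setdiff(spec$params, names(p))
  if (length(missing) > 0) {
    abort(sprintf("model '%s' needs parameter(s): %s", model,
                  paste(missing, collapse = ", ")),
          class = "thermoscape_config_error")
  }
  spec$fn(p, temp)
}

#' Quadratic-denominator Flinn-type curve
#'
#' Evaluates `speed = 1 / (1 + a + b*temp + c*temp^2)`. The denominator must
#' stay positive over the requested temperatures.
#'
#' @param a,b,c Curve coefficients.
#' @param temp Temperatures (degC).
#' @return Righting speed (s^-1).
#' @examples
#' flinn_eval(76.79, -4.45, 0.07, 31.786) # value at the analytic vertex
#' @export
flinn_eval <- function(a, b, c, temp) {
  den <- 1 + a + b * temp + c * temp^2
  if (any(den <= 0)) {
    abort("flinn denominator must be positive over `temp`",
          class = "thermoscape_domain_error")
  }
  1 / den
}
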