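## Nonlinear thermal-performance curves. Each model maps temperature (C) to
## developmental rate (1/day). Analytis and Briere-2 are zero outside
## [t_min, t_max]; Lactin-2 is a raw formula value whose thresholds are its
## zero crossings.

#' Analytis development-rate curve
#'
#' `rate = a * (T - t_min)^n * (t_max - T)^m` on `(t_min, t_max)`, zero
#' outside. The exponents `n` and `m` shape the rising and falling limbs;
#' the maximum has the closed form `T_fast = (n*t_max + m*t_min)/(n + m)`.
#'
#' @param temperature degrees C (vectorized).
#' @param a scale coefficient (> 0).
#' @param t_min,t_max lower and upper thresholds, `t_min < t_max`.
#' @param n,m limb exponents, `n > 0`, `m >= 0`.
#' @return rate, per day.
#' @export
rate_analytis <- function(temperature, a, t_min, t_max, n, m) {
  inside <- temperature > t_min & temperature < t_max
  out <- numeric(length(temperature))
  out[inside] <- a * (temperature[inside] - t_min)^n * (t_max - temperature[inside])^m
  ## at the boundaries the vanishing factor wins for positive exponents
  out[temperature == t_min] <- if (n > 0) 0 else a * (t_max - t_min)^m
  out[temperature == t_max] <- if (m > 0) 0 else a * (t_max - t_min)^n
  out
}

#' Briere-2 development-rate curve
#'
#' `rate = a * T * (T - t_min) * (t_max - T)^(1/d)` on `(t_min, t_max)`,
#' zero outside. The `1/d` exponent is applied only to the nonnegative base
#' `(t_max - T)`; a negative fitted `d` is accepted and evaluated as
#' written (the term then approaches `(t_max - T)^0` behaviour for large
#' `|d|`).
#'
#' @inheritParams rate_analytis
#' @param d exponent denominator, nonzero.
#' @return rate, per day.
#' @export
rate_briere2 <- function(temperature, a, t_min, t_max, d) {
  inside <- temperature > t_min & temperature < t_max
  out <- numeric(length(temperature))
  Ti <- temperature[inside]
  out[inside] <- a * Ti * (Ti - t_min) * (t_max - Ti)^(1 / d)
  out
}

#' Lactin-2 development-rate curve
#'
#' `rate = exp(p*T) - exp(p*t_max - (t_max - T)/delta_t) + lam`. Unlike the
#' other curves this is a raw formula value and may be negative; the
#' developmental thresholds are its zero crossings, and the fitted `t_max`
#' parameter plays the role of the upper threshold.
#'
#' @inheritParams rate_analytis
#' @param p rate-increase coefficient (per degree C).
#' @param delta_t width of the high-temperature decline (degrees C, > 0).
#' @param lam dimensionless vertical offset.
#' @param t_max_param upper-threshold parameter (degrees C).
#' @return formula value, per day (may be negative).
#' @export
rate_lactin2 <- function(temperature, p, delta_t, lam, t_max_param) {
  exp(p * temperature) -
    exp(p * t_max_param - (t_max_param - temperature) / delta_t) + lam
}

## Registry of fittable curves: parameter names, default bounds, which
## parameters start on a log scale, and the rate function on a named
## parameter vector. Default bounds bracket temperate-insect biology:
## thresholds 0-20 C (lower) and 30-45 C (upper), limb exponents in (0, 5],
## scale coefficients log-uniform over several decades.
tpc_models <- function() {
  list(
    analytis = list(
      par = c("a", "t_min", "t_max", "n", "m"),
      lower = c(a = 1e-9, t_min = 0, t_max = 30, n = 1e-6, m = 0),
      upper = c(a = 1, t_min = 20, t_max = 45, n = 5, m = 5),
      log_start = "a",
      fn = function(p, temperature)
        rate_analytis(temperature, p[["a"]], p[["t_min"]], p[["t_max"]],
                      p[["n"]], p[["m"]])),
    briere2 = list(
      par = c("a", "t_min", "t_max", "d"),
      lower = c(a = 1e-9, t_min = 0, t_max = 30, d = 1e-6),
      upper = c(a = 1, t_min = 20, t_max = 45, d = 5),
      log_start = "a",
      fn = function(p, temperature)
        rate_briere2(temperature, p[["a"]], p[["t_min"]], p[["t_max"]],
                     p[["d"]])),
    lactin2 = list(
      par = c("p", "delta_t", "lam", "t_max_param"),
      lower = c(p = 1e-4, delta_t = 0.5, lam = -2, t_max_param = 30),
      upper = c(p = 0.5, delta_t = 20, lam = 1, t_max_param = 45),
      log_start = character(),
      fn = function(p, temperature)
        rate_lactin2(temperature, p[["p"]], p[["delta_t"]], p[["lam"]],
                     p[["t_max_param"]]))
  )
}

#' Evaluate a registered rate curve
#'
#' @param model_id one of `"analytis"`, `"briere2"`, `"lactin2"`.
#' @param params named numeric vector (or list) of the model's parameters;
#'   see [rate_analytis()], [rate_briere2()], [rate_lactin2()] for names.
#' @param temperature degrees C (vectorized).
#' @return rate, per day.
#' @export
rate_curve <- function(model_id, params, temperature) {
  spec <- tpc_models()[[match.arg(model_id, names(tpc_models()))]]
  params <- unlist(params)
  missing <- setdiff(spec$par, names(params))
  if (length(missing) > 0)
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  spec$fn(params, temperature)
}
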