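## Linear degree-day models. Both are ordinary least squares on summary
## data; what differs is the regression variables and how the threshold and
## thermal constant fall out of the coefficients.
##
##  traditional:   1/D = -T_min/K + T/K      (rate on temperature)
##  Ikemoto-Takai: D*T = K + T_min * D       (duration*temperature on duration)

new_dd_linear_fit <- function(model_id, fit, slope, intercept, t_min, se_t_min,
                              k, se_k, n, flag = NA_character_) {
  ## noiseless inputs (simulated truth) are legitimate; silence lm's
  ## "essentially perfect fit" advisory
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(list(
    model_id = model_id,
    slope = unname(slope), intercept = unname(intercept),
    t_min = unname(t_min), se_t_min = unname(se_t_min),
    k = unname(k), se_k = unname(se_k),
    r2 = r2, r2_adj = r2_adj,
    p_value = unname(sm$coefficients[2, 4]),
    n_points = n,
    residual_mean_square = sm$sigma^2,
    flag = flag,
    lm = fit), class = "dd_linear_fit")
}

#' Fit the traditional linear degree-day model
#'
#' Ordinary least squares of developmental rate on temperature,
#' `1/D = a + b*T`. The lower developmental threshold is the x-intercept,
#' `T_min = -a/b`, and the thermal constant is `K = 1/b` degree-days.
#' Standard errors of the derived quantities come from [se_t_min()] and
#' [se_k()].
#'
#' A non-positive fitted slope leaves the threshold undefined; the result is
#' then returned with `flag = "nonpositive_slope"` and `NA` derived values
#' rather than an error, so batch runs over many stages complete.
#'
#' @param points data frame with `temperature` and `rate` columns, at least
#'   3 rows at 3 distinct temperatures.
#' @param weights optional case weights (e.g. the `weight` column holding
#'   sample sizes). Default unweighted, which is the convention for fits to
#'   per-temperature mean rates.
#' @return a `dd_linear_fit` with elements `slope`, `intercept`, `t_min`,
#'   `se_t_min`, `k`, `se_k`, `r2`, `r2_adj`, `p_value` (two-sided t test of
#'   the slope), `n_points`, `residual_mean_square` and `flag`.
#' @examples
#' pts <- data.frame(temperature = c(20, 24, 28, 30),
#'                   rate = 0.01 * (c(20, 24, 28, 30) - 15))
#' fit_traditional(pts)  # recovers t_min = 15, k = 100 exactly
#' @export
fit_traditional <- function(points, weights = NULL) {
  check_regression_input(points$temperature, points$rate)
  fit <- stats::lm(rate ~ temperature, data = points, weights = weights)
  b <- stats::coef(fit)[2]; a <- stats::coef(fit)[1]
  n <- nrow(points)
  if (!is.finite(b) || b <= 0) {
    return(new_dd_linear_fit("traditional", fit, b, a,
                             NA_real_, NA_real_, NA_real_, NA_real_, n,
                             flag = "nonpositive_slope"))
  }
  se_b <- suppressWarnings(summary(fit))$coefficients[2, 2]
  s2 <- sum(stats::resid(fit)^2) / (n - 2)
  r_bar <- mean(points$rate)
  new_dd_linear_fit("traditional", fit, b, a,
                    t_min = -a / b,
                    se_t_min = se_t_min(r_bar, s2, n, b, se_b),
                    k = 1 / b, se_k = se_k(b, se_b), n = n)
}

#' Fit the Ikemoto-Takai linearization
#'
#' Ordinary least squares of the product `D*T` on duration `D`,
#' `D*T = K + T_min * D`. The slope *is* the lower threshold estimate and
#' the intercept *is* the thermal constant, so their standard errors are the
#' usual regression coefficient SEs. This reformulation was proposed to give
#' more stable threshold and thermal-constant estimates than the traditional
#' rate-on-temperature line.
#'
#' @param durations data frame with `temperature` and `duration` columns
#'   (days), at least 3 rows.
#' @param weights optional case weights; default unweighted.
#' @return a `dd_linear_fit`; see [fit_traditional()] for the fields.
#'   `slope` and `t_min` coincide, as do `intercept` and `k`.
#' @examples
#' d <- data.frame(temperature = c(20, 24, 28, 30),
#'                 duration = c(6.52, 4.76, 3.71, 3.00))
#' fit_ikemoto_takai(d)
#' @export
fit_ikemoto_takai <- function(durations, weights = NULL) {
  check_regression_input(durations$duration, durations$temperature)
  df <- data.frame(D = durations$duration,
                   DT = durations$duration * durations$temperature)
  fit <- stats::lm(DT ~ D, data = df, weights = weights)
  cf <- suppressWarnings(summary(fit))$coefficients
  n <- nrow(df)
  flag <- if (cf[2, 1] <= 0) "nonpositive_slope" else NA_character_
  new_dd_linear_fit("ikemoto_takai", fit,
                    slope = cf[2, 1], intercept = cf[1, 1],
                    t_min = cf[2, 1], se_t_min = cf[2, 2],
                    k = cf[1, 1], se_k = cf[1, 2], n = n, flag = flag)
}

check_regression_input <- function(x, y) {
  if (length(x) < 3 || length(y) < 3)
    stop("at least 3 points are required", call. = FALSE)
  if (length(unique(x)) < 3)
    stop("at least 3 distinct predictor values are required", call. = FALSE)
  invisible(TRUE)
}

#' Standard error of the lower threshold from a rate-on-temperature line
#'
#' Delta-method SE of `T_min = -a/b` for the traditional model:
#' `(r_bar/b) * sqrt(S2/(N*r_bar^2) + SE_b^2/b^2)`, where `r_bar` is the
#' sample mean rate, `S2` the residual mean square, `N` the number of
#' points, `b` the slope and `SE_b` its standard error.
#'
#' @param r_bar mean observed rate (per day).
#' @param s2 residual mean square of the regression.
#' @param n number of points.
#' @param b slope; must be nonzero.
#' @param se_b standard error of the slope.
#' @return SE of `T_min` in degrees C.
#' @export
se_t_min <- function(r_bar, s2, n, b, se_b) {
  if (!is.finite(b) || b == 0) stop("zero slope: T_min undefined", call. = FALSE)
  stopifnot(n >= 3)
  (r_bar / b) * sqrt(s2 / (n * r_bar^2) + se_b^2 / b^2)
}

#' Standard error of the thermal constant
#'
#' Delta-method SE of `K = 1/b`: `SE_K = SE_b / b^2`.
#'
#' @inheritParams se_t_min
#' @return SE of `K` in degree-days.
#' @export
se_k <- function(b, se_b) {
  if (!is.finite(b) || b == 0) stop("zero slope: K undefined", call. = FALSE)
  se_b / b^2
}

#' Predicted development duration from a degree-day fit
#'
#' Inverts the degree-day relation: `D = K / (T - T_min)` days. Only defined
#' above the threshold.
#'
#' @param fit a `dd_linear_fit`.
#' @param temperature degrees C, must exceed `fit$t_min`.
#' @return predicted duration in days.
#' @export
predict_duration <- function(fit, temperature) {
  stopifnot(inherits(fit, "dd_linear_fit"))
  if (!is.finite(fit$t_min)) stop("fit has no defined threshold", call. = FALSE)
  if (any(temperature <= fit$t_min))
    stop("temperature at or below t_min: duration undefined", call. = FALSE)
  fit$k / (temperature - fit$t_min)
}

#' @export
print.dd_linear_fit <- function(x, ...) {
  eq <- if (x$model_id == "traditional") {
    sprintf("1/D = %.5g + %.5g T", x$intercept, x$slope)
  } else {
    sprintf("DT = %.5g + %.5g D", x$intercept, x$slope)
  }
  cat(sprintf("<dd_linear_fit: %s>  %s\n", x$model_id, eq))
  cat(sprintf("  T_min = %.3f +/- %.3f C   K = %.2f +/- %.2f DD\n",
              x$t_min, x$se_t_min, x$k, x$se_k))
  cat(sprintf("  R2 = %.4f  R2_adj = %.4f  P = %.4g  (n = %d)\n",
              x$r2, x$r2_adj, x$p_value, x$n_points))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
as.data.frame.dd_linear_fit <- function(x, ...) {
  data.frame(model_id = x$model_id, slope = x$slope, intercept = x$intercept,
             t_min = x$t_min, se_t_min = x$se_t_min, k = x$k, se_k = x$se_k,
             r2 = x$r2, r2_adj = x$r2_adj, p_value = x$p_value,
             n_points = x$n_points, flag = x$flag)
}
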