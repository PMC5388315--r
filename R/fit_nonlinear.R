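## Multi-start bounded least squares for the thermal-performance curves.
## Four- and five-parameter curves fitted to a handful of mean rates have
## many local optima, so every fit launches a Latin-hypercube batch of
## starts inside the bounds and keeps the best converged solution;
## determinism comes from the seed.

#' Fit a nonlinear thermal-performance curve
#'
#' Least-squares fit of an Analytis, Briere-2 or Lactin-2 curve to
#' developmental-rate points by bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) from `n_starts` Latin-hypercube starting points
#' within the bounds. Scale coefficients start log-uniformly. The best
#' (lowest residual sum of squares) converged start wins; the whole
#' procedure is deterministic given `seed`.
#'
#' Fits with fewer points than parameters are permitted (the curves are
#' routinely fitted to 5 rate means); the adjusted R-squared is then
#' undefined and reported as `NaN`.
#'
#' @param points data frame with `temperature` and `rate` columns, at least
#'   3 rows.
#' @param model `"analytis"`, `"briere2"` or `"lactin2"`.
#' @param lower,upper optional named bounds overriding the defaults in the
#'   model registry (see [rate_curve()]); must be finite.
#' @param n_starts number of Latin-hypercube starts (default 64).
#' @param seed RNG seed for the start design (default 20170228).
#' @return a `tpc_fit`: `model_id`, named `par`, `rss`, `r2`, `r2_adj`
#'   (with `k` = number of free parameters), `n_points`, `converged`,
#'   `n_starts_used`, `at_bounds` (names of parameters within 1e-6 of a
#'   bound -- a boundary solution is a warning sign), and `critical`
#'   ([critical_temperatures()] of the fitted curve).
#' @examples
#' pts <- data.frame(temperature = c(20, 24, 28, 30, 32),
#'                   rate = 1 / c(46.62, 29.34, 24.47, 22.04, 22.43))
#' fit <- fit_rate_curve(pts, "briere2")
#' fit$critical$t_fast
#' @export
fit_rate_curve <- function(points, model = c("analytis", "briere2", "lactin2"),
                           lower = NULL, upper = NULL,
                           n_starts = 64, seed = 20170228) {
  model <- match.arg(model)
  if (nrow(points) < 3) stop("at least 3 points are required", call. = FALSE)
  spec <- tpc_models()[[model]]
  lo <- spec$lower; hi <- spec$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("bounds must be finite with lower < upper", call. = FALSE)

  temperature <- points$temperature
  rate <- points$rate
  resid_fn <- function(p) {
    names(p) <- spec$par
    r <- rate - spec$fn(p, temperature)
    if (any(!is.finite(r))) r[] <- 1e6
    r
  }

  design <- with_seed(seed, lhs::randomLHS(n_starts, length(spec$par)))
  best <- NULL
  n_used <- 0L
  for (i in seq_len(n_starts)) {
    st <- lo + design[i, ] * (hi - lo)
    for (pn in spec$log_start) {
      j <- match(pn, spec$par)
      st[j] <- exp(log(lo[j]) + design[i, j] * (log(hi[j]) - log(lo[j])))
    }
    out <- tryCatch(
      minpack.lm::nls.lm(st, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(out)) next
    n_used <- n_used + 1L
    v <- sum(out$fvec^2)
    if (is.finite(v) && (is.null(best) || v < best$rss))
      best <- list(rss = v, par = stats::setNames(stats::coef(out), spec$par))
  }
  if (is.null(best)) {
    return(structure(list(model_id = model, par = stats::setNames(
      rep(NA_real_, length(spec$par)), spec$par),
      rss = NA_real_, r2 = NA_real_, r2_adj = NA_real_,
      n_points = nrow(points), converged = FALSE, n_starts_used = n_used,
      at_bounds = character(), critical = NULL), class = "tpc_fit"))
  }

  fitted <- spec$fn(best$par, temperature)
  gof <- r2_adjusted(rate, fitted, k = length(spec$par))
  tol <- 1e-6 * pmax(1, abs(hi - lo))
  at_bounds <- spec$par[best$par - lo < tol | hi - best$par < tol]
  structure(list(model_id = model, par = best$par,
                 rss = best$rss, r2 = gof$r2, r2_adj = gof$r2_adj,
                 n_points = nrow(points), converged = TRUE,
                 n_starts_used = n_used, at_bounds = at_bounds,
                 critical = critical_temperatures(model, best$par)),
            class = "tpc_fit")
}

#' Critical temperatures of a fitted (or given) rate curve
#'
#' Derives the lower threshold `t_min`, upper threshold `t_max` and
#' fastest-development temperature `t_fast` (the argmax of the rate curve):
#'
#' * Analytis, Briere-2: `t_min` and `t_max` are the fitted parameters;
#'   `t_fast` by golden-section maximization on `[t_min, t_max]` to 1e-6
#'   degrees C. For Analytis the closed form
#'   `(n*t_max + m*t_min)/(n + m)` agrees with the numeric argmax.
#' * Lactin-2: `t_max` is reported as the fitted `t_max_param`; `t_fast` by
#'   golden-section maximization; `t_min` is the lower zero crossing of the
#'   formula below `t_fast`, found by bracketed root search. With no sign
#'   change below `t_fast`, `t_min` is `NA` and the provenance flags it.
#'
#' @param model_or_fit a `tpc_fit`, or a model id string.
#' @param params named parameter vector (only when a model id was given).
#' @return list with `t_min`, `t_max`, `t_fast` and `provenance` (named
#'   character: how each value was obtained).
#' @export
critical_temperatures <- function(model_or_fit, params = NULL) {
  if (inherits(model_or_fit, "tpc_fit")) {
    model <- model_or_fit$model_id
    params <- model_or_fit$par
  } else {
    model <- match.arg(model_or_fit, names(tpc_models()))
    params <- unlist(params)
  }
  spec <- tpc_models()[[model]]
  f <- function(tt) spec$fn(params, tt)

  if (model %in% c("analytis", "briere2")) {
    t_min <- params[["t_min"]]; t_max <- params[["t_max"]]
    t_fast <- maximize_on(f, t_min, t_max, tol = 1e-6)$maximum
    list(t_min = t_min, t_max = t_max, t_fast = t_fast,
         provenance = c(t_min = "fitted-parameter",
                        t_max = "fitted-parameter",
                        t_fast = "numeric-argmax"))
  } else {
    t_max <- params[["t_max_param"]]
    t_fast <- maximize_on(f, t_max - 60, t_max, tol = 1e-6)$maximum
    t_min <- NA_real_
    prov_min <- "undefined-no-sign-change"
    lo_grid <- seq(t_fast, t_fast - 60, by = -0.25)
    vals <- f(lo_grid)
    j <- which(vals <= 0)[1]
    if (!is.na(j) && j > 1) {
      t_min <- stats::uniroot(f, c(lo_grid[j], lo_grid[j - 1]),
                              tol = 1e-8)$root
      prov_min <- "numeric-root"
    }
    list(t_min = t_min, t_max = t_max, t_fast = t_fast,
         provenance = c(t_min = prov_min, t_max = "fitted-parameter",
                        t_fast = "numeric-argmax"))
  }
}

#' Closed-form fastest-development temperature of the Analytis curve
#'
#' `T_fast = (n*t_max + m*t_min)/(n + m)`; used as an independent check of
#' the numeric argmax.
#'
#' @param t_min,t_max thresholds, degrees C.
#' @param n,m limb exponents.
#' @return degrees C.
#' @export
analytis_t_fast <- function(t_min, t_max, n, m) {
  (n * t_max + m * t_min) / (n + m)
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("<tpc_fit: %s>  %s\n", x$model_id,
              if (x$converged) "converged" else "NOT converged"))
  if (x$converged) {
    cat("  ", paste(sprintf("%s = %.6g", names(x$par), x$par), collapse = ", "),
        "\n", sep = "")
    cat(sprintf("  rss = %.4g  R2_adj = %.4f  (n = %d, starts = %d)\n",
                x$rss, x$r2_adj, x$n_points, x$n_starts_used))
    cat(sprintf("  t_min = %.2f  t_max = %.2f  t_fast = %.2f\n",
                x$critical$t_min, x$critical$t_max, x$critical$t_fast))
    if (length(x$at_bounds) > 0)
      cat("  at bounds:", paste(x$at_bounds, collapse = ", "), "\n")
  }
  invisible(x)
}
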