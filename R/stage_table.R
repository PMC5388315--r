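## Stage-duration tables: the empirical record of a constant-temperature
## rearing experiment. One row per (life stage, temperature) with the mean
## development duration of survivors, its SE, the number of individuals
## entering the stage, and the fraction surviving it.

STAGE_LEVELS <- c("egg", paste0("larva_", c("I", "II", "III", "IV", "V", "VI")),
                  "larvae_total", "prepupa", "pupa", "immature_total")

#' Construct and validate a stage-duration table
#'
#' A `stage_table` is a validated data frame with columns `stage`,
#' `temperature_C`, `mean_duration_d`, `se_d`, `n` and `survival`
#' (`se_d` and `survival` may be `NA`). Durations are in days, temperatures
#' in degrees Celsius, survival a fraction in `[0, 1]`.
#'
#' @param x data frame with the columns above.
#' @param metadata optional character notes on provenance, kept as an
#'   attribute.
#' @return the validated data frame with class `stage_table`.
#' @examples
#' tab <- stage_table(data.frame(
#'   stage = "egg", temperature_C = c(20, 24, 28),
#'   mean_duration_d = c(6.5, 4.8, 3.7), se_d = NA, n = 100, survival = 0.9))
#' @export
stage_table <- function(x, metadata = character()) {
  required <- c("stage", "temperature_C", "mean_duration_d", "se_d", "n", "survival")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- as.data.frame(x)[required]
  if (nrow(x) == 0) stop("no observations", call. = FALSE)

  x$stage <- as.character(x$stage)
  for (col in c("temperature_C", "mean_duration_d", "se_d", "n", "survival"))
    x[[col]] <- as.numeric(x[[col]])

  bad_stage <- !x$stage %in% STAGE_LEVELS
  bad_dur <- !is.finite(x$mean_duration_d) | x$mean_duration_d <= 0
  bad_n <- !is.finite(x$n) | x$n < 1
  bad_surv <- !is.na(x$survival) & (x$survival < 0 | x$survival > 1)
  problems <- character()
  report <- function(mask, what)
    if (any(mask)) sprintf("row %d: %s", which(mask), what)
  problems <- c(problems,
                report(bad_stage, "unknown stage label"),
                report(bad_dur, "mean_duration_d must be a positive number"),
                report(bad_n, "n must be >= 1"),
                report(bad_surv, "survival must lie in [0, 1]"))
  dup <- duplicated(x[c("stage", "temperature_C")])
  problems <- c(problems, report(dup, "duplicate (stage, temperature) pair"))
  if (length(problems) > 0)
    stop("invalid stage table:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)

  x <- x[order(match(x$stage, STAGE_LEVELS), x$temperature_C), ]
  rownames(x) <- NULL
  structure(x, metadata = as.character(metadata),
            class = c("stage_table", "data.frame"))
}

#' Read a stage-duration table from CSV
#'
#' The canonical schema has the header
#' `stage,temperature_C,mean_duration_d,se_d,n,survival`. Survival may be
#' recorded either as a fraction in `[0, 1]` or as a percentage; the
#' `survival` argument states which explicitly (no guessing).
#'
#' @param path path to a CSV file.
#' @param survival `"fraction"` (default) or `"percent"`; how the survival
#'   column is encoded in the file.
#' @return a [stage_table()].
#' @seealso [write_stage_table()], [glyphodes_table1()]
#' @export
read_stage_table <- function(path, survival = c("fraction", "percent")) {
  survival <- match.arg(survival)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(x) == 0) stop("no observations", call. = FALSE)
  if (survival == "percent" && "survival" %in% names(x))
    x$survival <- as.numeric(x$survival) / 100
  stage_table(x, metadata = paste0("read from ", basename(path)))
}

#' Write a stage-duration table to CSV
#'
#' Inverse of [read_stage_table()]: the written file re-reads to an
#' identical table. Survival is always written as a fraction.
#'
#' @param x a [stage_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(x, path) {
  stopifnot(inherits(x, "stage_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' The bundled mulberry pyralid rearing dataset
#'
#' Stage-specific development times (means of survivors, with SE), sample
#' sizes and survival of the lesser mulberry pyralid reared on mulberry
#' leaves at constant temperatures of 16-32 degrees C. Larvae passed through
#' five stadia at 20-28 degrees C and six at 16, 30 and 32 degrees C, so the
#' `larva_VI` rows exist only at those temperatures. For `immature_total`
#' (egg to adult emergence) the sample size is the number of eggs that
#' started the cohort and survival is the cumulative egg-to-adult fraction
#' (the product of the stage survivals, e.g. only 4% of the cohort completed
#' development at 16 degrees C).
#'
#' @return a [stage_table()].
#' @examples
#' tab <- glyphodes_table1()
#' subset(tab, stage == "immature_total")
#' @export
glyphodes_table1 <- function() {
  path <- system.file("extdata", "glyphodes_table1.csv", package = "thermaldev",
                      mustWork = TRUE)
  read_stage_table(path)
}

#' @export
print.stage_table <- function(x, ...) {
  cat(sprintf("<stage_table> %d observations, %d stage(s), %d temperature(s)\n",
              nrow(x), length(unique(x$stage)), length(unique(x$temperature_C))))
  meta <- attr(x, "metadata")
  if (length(meta) > 0) cat("  ", meta, "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Developmental rates of one stage
#'
#' Converts the mean development duration of a stage at each temperature to
#' a developmental rate, the reciprocal of the mean duration (1/D, per day).
#' The reciprocal of the mean -- not the mean of individual reciprocals --
#' is the quantity the degree-day framework linearizes.
#'
#' @param table a [stage_table()].
#' @param stage stage label present in `table`.
#' @return data frame with columns `temperature`, `rate`, `weight` (the
#'   sample size `n`, usable for weighted fits) and `survival`.
#' @examples
#' pts <- compute_rates(glyphodes_table1(), "immature_total")
#' @export
compute_rates <- function(table, stage) {
  stopifnot(inherits(table, "stage_table"))
  rows <- table[table$stage == stage, ]
  if (nrow(rows) == 0)
    stop("unknown stage: ", stage, " (table has: ",
         paste(unique(table$stage), collapse = ", "), ")", call. = FALSE)
  data.frame(temperature = rows$temperature_C,
             rate = 1 / rows$mean_duration_d,
             weight = rows$n,
             survival = rows$survival)
}

#' Restrict rate points to the usable (near-linear) temperature range
#'
#' Degree-day regressions are only valid on the rising, near-linear segment
#' of the rate curve. Two exclusion rules are applied:
#'
#' * temperatures whose survival falls below `min_survival` are dropped
#'   (development observed on a handful of stressed survivors does not
#'   represent the population);
#' * when `exclude_above_peak` is set, every temperature strictly above the
#'   temperature of the maximum observed rate is dropped, because beyond the
#'   peak the rate falls and the linear model no longer applies.
#'
#' Survival defaults to the `survival` column of `points`; supplying
#' `survival_by_temp` overrides it, which is how whole-cohort (egg-to-adult)
#' survival can govern the selection for every stage: a temperature at which
#' the cohort cannot complete development is unusable for any stage.
#'
#' @param points data frame with `temperature` and `rate` columns (as from
#'   [compute_rates()]).
#' @param survival_by_temp optional named numeric vector, names are
#'   temperatures, values survival fractions.
#' @param min_survival survival fraction below which a temperature is
#'   dropped; default 0.05.
#' @param exclude_above_peak drop temperatures above the observed rate
#'   maximum; default `TRUE` (appropriate for linear fits; set `FALSE` for
#'   nonlinear fits, which need the descending limb).
#' @return the retained subset of `points`; errors if fewer than 3 points
#'   remain.
#' @export
select_linear_range <- function(points, survival_by_temp = NULL,
                                min_survival = 0.05, exclude_above_peak = TRUE) {
  stopifnot(is.data.frame(points), nrow(points) > 0)
  keep <- rep(TRUE, nrow(points))
  surv <- if (!is.null(survival_by_temp)) {
    as.numeric(survival_by_temp[as.character(points$temperature)])
  } else if ("survival" %in% names(points)) {
    points$survival
  } else {
    rep(NA_real_, nrow(points))
  }
  keep <- keep & (is.na(surv) | surv >= min_survival)
  if (exclude_above_peak && any(keep)) {
    t_peak <- points$temperature[keep][which.max(points$rate[keep])]
    keep <- keep & points$temperature <= t_peak
  }
  out <- points[keep, , drop = FALSE]
  if (nrow(out) < 3)
    stop("fewer than 3 points remain after range selection", call. = FALSE)
  rownames(out) <- NULL
  out
}
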