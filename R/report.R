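## Publication-style summary tables: one row per stage and linear model
## (threshold/thermal-constant table) and a long parameter table for the
## nonlinear fits, plus CSV/JSON writers carrying full provenance.

cohort_survival <- function(table) {
  ## whole-cohort (egg-to-adult) survival governs range selection for every
  ## stage when available; a temperature the cohort cannot complete is
  ## unusable for any stage.
  src <- if ("immature_total" %in% table$stage) "immature_total" else NULL
  if (is.null(src)) return(NULL)
  rows <- table[table$stage == src, ]
  stats::setNames(rows$survival, rows$temperature_C)
}

#' Linear-model summary table for all stages
#'
#' Applies the exclusion rules of [select_linear_range()] (survival below
#' `min_survival` -- judged on whole-cohort survival when an
#' `immature_total` stage is present -- and the above-peak rule), then fits
#' both linear models per stage on the retained temperatures.
#'
#' @param table a [stage_table()].
#' @param stages stages to fit; default the composite stages present among
#'   egg, larvae_total, prepupa, pupa, immature_total.
#' @param include_temperatures optional explicit inclusion set (degrees C)
#'   overriding the rules.
#' @param min_survival,exclude_above_peak see [select_linear_range()].
#' @param weighted weight the fits by sample size (default `FALSE`, the
#'   convention for fits to mean rates).
#' @return data frame, one row per (stage, model): regression equation,
#'   `r2`, `r2_adj`, `p_value`, `t_min`, `se_t_min`, `k`, `se_k`,
#'   `n_points`, `temperatures_used`, `flag`. Attribute `"exclusions"`
#'   records every dropped temperature and why.
#' @export
fit_linear_report <- function(table, stages = NULL, include_temperatures = NULL,
                              min_survival = 0.05, exclude_above_peak = TRUE,
                              weighted = FALSE) {
  stopifnot(inherits(table, "stage_table"))
  if (is.null(stages))
    stages <- intersect(c("egg", "larvae_total", "prepupa", "pupa",
                          "immature_total"), unique(table$stage))
  if (length(stages) == 0) stop("no stages to fit", call. = FALSE)
  unknown <- setdiff(stages, unique(table$stage))
  if (length(unknown) > 0)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  surv_map <- cohort_survival(table)

  rows <- list(); exclusions <- list()
  for (st in stages) {
    pts <- compute_rates(table, st)
    if (!is.null(include_temperatures)) {
      sel <- pts[pts$temperature %in% include_temperatures, , drop = FALSE]
      if (nrow(sel) < 3)
        stop("fewer than 3 points in the inclusion set for stage ", st,
             call. = FALSE)
    } else {
      sel <- select_linear_range(pts, survival_by_temp = surv_map,
                                 min_survival = min_survival,
                                 exclude_above_peak = exclude_above_peak)
    }
    dropped <- setdiff(pts$temperature, sel$temperature)
    if (length(dropped) > 0)
      exclusions[[st]] <- data.frame(stage = st, temperature = dropped)
    w <- if (weighted) sel$weight else NULL
    durs <- table[table$stage == st & table$temperature_C %in% sel$temperature, ]
    fits <- list(
      fit_traditional(sel, weights = w),
      fit_ikemoto_takai(data.frame(temperature = durs$temperature_C,
                                   duration = durs$mean_duration_d),
                        weights = w))
    for (f in fits) {
      df <- as.data.frame(f)
      df$equation <- if (f$model_id == "traditional")
        sprintf("1/D = %.5g + %.5g T", f$intercept, f$slope)
      else sprintf("DT = %.5g + %.5g D", f$intercept, f$slope)
      df$stage <- st
      df$temperatures_used <- paste(sel$temperature, collapse = ",")
      rows[[length(rows) + 1]] <- df
    }
  }
  out <- do.call(rbind, rows)
  out <- out[c("stage", "model_id", "equation", "r2", "r2_adj", "p_value",
               "t_min", "se_t_min", "k", "se_k", "n_points",
               "temperatures_used", "flag")]
  attr(out, "exclusions") <- if (length(exclusions) > 0)
    do.call(rbind, exclusions) else NULL
  out
}

#' Nonlinear-model summary table for all stages
#'
#' Fits the requested thermal-performance curves (and optionally the SSI
#' model) per stage on the survival-filtered temperature range (the
#' descending limb is kept: nonlinear curves need it).
#'
#' @inheritParams fit_linear_report
#' @param models character subset of
#'   `c("analytis", "briere2", "lactin2", "ssi")`.
#' @param seed seed passed to every fit.
#' @return long data frame: `stage`, `model`, `parameter`, `value`. Fitted
#'   parameters are followed by `t_min`, `t_max`, `t_fast` (and for SSI
#'   `t_opt`, `chi_square`), then `rss`, `r2_adj`, `converged`.
#' @export
fit_nonlinear_report <- function(table, stages = NULL,
                                 models = c("analytis", "briere2", "lactin2", "ssi"),
                                 min_survival = 0.05, seed = 20170228) {
  stopifnot(inherits(table, "stage_table"))
  if (length(models) == 0) stop("no models requested", call. = FALSE)
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(stages))
    stages <- intersect(c("egg", "larvae_total", "prepupa", "pupa",
                          "immature_total"), unique(table$stage))
  surv_map <- cohort_survival(table)

  rows <- list()
  add <- function(stage, model, parameter, value)
    rows[[length(rows) + 1]] <<- data.frame(stage = stage, model = model,
                                            parameter = parameter,
                                            value = value)
  for (st in stages) {
    pts <- compute_rates(table, st)
    sel <- select_linear_range(pts, survival_by_temp = surv_map,
                               min_survival = min_survival,
                               exclude_above_peak = FALSE)
    for (m in models) {
      if (m == "ssi") {
        fit <- fit_ssi(sel, seed = seed)
        if (fit$converged) {
          p <- fit$params
          for (nm in c("rho_phi", "t_opt", "t_l", "t_h", "dh_a", "dh_l", "dh_h"))
            add(st, m, nm, p[[nm]])
          add(st, m, "t_fast", fit$t_fast)
          add(st, m, "chi_square", fit$chi_square)
          add(st, m, "rss", fit$rss)
          add(st, m, "r2_adj", fit$r2_adj)
        }
        add(st, m, "converged", as.numeric(fit$converged))
      } else {
        fit <- fit_rate_curve(sel, m, seed = seed)
        if (fit$converged) {
          for (nm in names(fit$par)) add(st, m, nm, fit$par[[nm]])
          add(st, m, "t_min", fit$critical$t_min)
          add(st, m, "t_max", fit$critical$t_max)
          add(st, m, "t_fast", fit$critical$t_fast)
          add(st, m, "rss", fit$rss)
          add(st, m, "r2_adj", fit$r2_adj)
        }
        add(st, m, "converged", as.numeric(fit$converged))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Write summary reports with provenance
#'
#' Writes `table2.csv` (linear report), `table3.csv` (nonlinear report) and
#' `fits.json` into `dir`. The JSON carries full provenance: package
#' version, MD5 checksum of the input file (when given), the seed and the
#' inclusion sets, so a report can be reproduced exactly.
#'
#' @param linear report from [fit_linear_report()], or `NULL`.
#' @param nonlinear report from [fit_nonlinear_report()], or `NULL`.
#' @param dir output directory (created if needed).
#' @param input_path optional path of the source CSV, checksummed into the
#'   provenance block.
#' @param seed seed recorded in the provenance block.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(linear = NULL, nonlinear = NULL, dir,
                          input_path = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(provenance = list(
    package = "thermaldev",
    version = as.character(utils::packageVersion("thermaldev")),
    input = if (!is.null(input_path)) basename(input_path) else NULL,
    input_md5 = if (!is.null(input_path))
      unname(tools::md5sum(input_path)) else NULL,
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)))
  if (!is.null(linear)) {
    utils::write.csv(linear, file.path(dir, "table2.csv"), row.names = FALSE,
                     na = "")
    payload$linear <- linear
    excl <- attr(linear, "exclusions")
    if (!is.null(excl)) payload$provenance$exclusions <- excl
  }
  if (!is.null(nonlinear)) {
    utils::write.csv(nonlinear, file.path(dir, "table3.csv"),
                     row.names = FALSE, na = "")
    payload$nonlinear <- nonlinear
  }
  jsonlite::write_json(payload, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
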