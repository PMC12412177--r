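## End-to-end drivers: from a collection of ATD traces to a calibration
## curve (calibrate_traces) and from traces + curve to CCS results
## (process_traces). These are what the command-line interface calls.

#' Run configuration
#'
#' Bundles the tunable settings of the calibration pipeline.
#'
#' @param mode `"multipass"` (drift value = t_pp) or `"single-pass"`
#'   (drift value = t_p1).
#' @param min_points Minimum included points per calibrant linear model
#'   (default 6; must be >= 3).
#' @param min_passes Advisory minimum passes per calibrant (default 4;
#'   must be >= 1).
#' @param gas_mass Buffer gas mass in Da (default nitrogen, 28.0134).
#' @param strict Strict input checking: bypass trace must sit exactly at
#'   `bypass_ts` and the four-pass advisory becomes an error.
#' @param bypass_ts Nominal bypass separation time, ms.
#' @param bypass_tol Accepted bypass t_s interval in lenient mode, ms.
#' @param single_pass_ts Separation time of the single-pass reference run;
#'   `NULL` = the smallest non-bypass separation time per analyte.
#' @param extrapolation_factor Drift-range excursion allowed before the
#'   extrapolation flag (default 1.5).
#' @param width_mult Primary-peak window width in FWHM multiples.
#' @param baseline Fit a constant ATD baseline (default TRUE).
#' @param dead_time Constant dead-time subtraction before power-law
#'   fitting, ms (default 0).
#' @param timestamp Write a timestamp comment line in result files.
#' @return A `ccs_config` list.
#' @export
ccs_config <- function(mode = c("multipass", "single-pass"),
                       min_points = 6L, min_passes = 4L,
                       gas_mass = 28.0134, strict = FALSE,
                       bypass_ts = 0.01, bypass_tol = c(0.005, 0.05),
                       single_pass_ts = NULL, extrapolation_factor = 1.5,
                       width_mult = 6, baseline = TRUE, dead_time = 0,
                       timestamp = FALSE) {
  mode <- match.arg(mode)
  if (min_points < 3L) stop("min_points must be >= 3", call. = FALSE)
  if (min_passes < 1L) stop("min_passes must be >= 1", call. = FALSE)
  if (gas_mass <= 0) stop("gas_mass must be > 0", call. = FALSE)
  structure(list(mode = mode, min_points = as.integer(min_points),
                 min_passes = as.integer(min_passes), gas_mass = gas_mass,
                 strict = isTRUE(strict), bypass_ts = bypass_ts,
                 bypass_tol = bypass_tol, single_pass_ts = single_pass_ts,
                 extrapolation_factor = extrapolation_factor,
                 width_mult = width_mult, baseline = isTRUE(baseline),
                 dead_time = dead_time, timestamp = isTRUE(timestamp)),
            class = "ccs_config")
}

split_traces_by_analyte <- function(traces) {
  ids <- vapply(traces, `[[`, character(1), "analyte_id")
  split(traces, factor(ids, levels = unique(ids)))
}

## Per-analyte drift extraction: bypass, t_p1, separation series, and the
## perturbation model (multipass mode only).
analyte_drift <- function(traces, config) {
  ts <- vapply(traces, `[[`, numeric(1), "separation_time")
  analyte <- traces[[1]]$analyte_id
  is_bypass <- if (config$strict) {
    abs(ts - config$bypass_ts) < 1e-9
  } else {
    ts >= config$bypass_tol[1] & ts <= config$bypass_tol[2]
  }
  if (!any(is_bypass)) {
    stop("analyte '", analyte, "': no bypass acquisition (t_s ~ ",
         config$bypass_ts, " ms) found", call. = FALSE)
  }
  bp_trace <- traces[is_bypass][[which.min(ts[is_bypass])]]
  bypass <- measure_bypass(bp_trace, bypass_ts = config$bypass_ts,
                           strict = config$strict, tol = config$bypass_tol)
  rest <- traces[!is_bypass]
  ts_rest <- ts[!is_bypass]
  if (!length(rest)) {
    stop("analyte '", analyte, "': only a bypass acquisition present",
         call. = FALSE)
  }
  sp_idx <- if (!is.null(config$single_pass_ts)) {
    which(abs(ts_rest - config$single_pass_ts) < 1e-9)[1]
  } else {
    which.min(ts_rest)
  }
  if (is.na(sp_idx)) {
    stop("analyte '", analyte, "': no acquisition at the single-pass ",
         "separation time ", config$single_pass_ts, " ms", call. = FALSE)
  }
  sp_trace <- rest[[sp_idx]]
  t_p1 <- fit_gaussian(sp_trace,
                       window = pick_primary_peak(sp_trace,
                                                  config$width_mult),
                       baseline = config$baseline)$center
  multi <- rest[-sp_idx]
  model <- NULL; series <- NULL
  if (config$mode == "multipass") {
    if (!length(multi)) {
      stop("analyte '", analyte, "': no multipass acquisitions",
           call. = FALSE)
    }
    series <- build_separation_series(multi, bypass, t_p1,
                                      min_passes = config$min_passes,
                                      width_mult = config$width_mult)
    model <- fit_perturbation_model(series, min_points = config$min_points,
                                    bypass = bypass, t_p1 = t_p1)
  }
  list(analyte = analyte, bypass = bypass, t_p1 = t_p1, series = series,
       model = model,
       drift = if (config$mode == "multipass") model$t_pp else t_p1,
       mz = traces[[1]]$mz, charge = traces[[1]]$charge)
}

#' Build a calibration curve from raw traces
#'
#' Full calibration driver: groups ATD traces by analyte, extracts per
#' calibrant the bypass time, single-pass arrival time and (in multipass
#' mode) the perturbation-corrected periodic drift time, then fits the
#' power-law calibration curve across calibrants.
#'
#' @param traces Named list of [atd_trace] (e.g. from
#'   [read_atd_workbook] or [generate_dataset]); each calibrant needs a
#'   bypass run, a single-pass run and, in multipass mode, enough
#'   multipass runs for its linear model.
#' @param calibrants Calibrant table (`name`, `mz`, `charge`, `ccs_ref`),
#'   e.g. from [read_calibrant_list].
#' @param config A [ccs_config].
#' @return A `ccs_calibration` (see [build_curve]) with an extra
#'   `models` field: the per-calibrant linear-model table (`analyte`,
#'   `t_pp`, `intercept`, `r_squared`, `n_points`, `bypass`, `t_p1`).
#' @export
calibrate_traces <- function(traces, calibrants, config = ccs_config()) {
  stopifnot(inherits(config, "ccs_config"))
  cal <- as.data.frame(calibrants)
  by_analyte <- split_traces_by_analyte(traces)
  absent <- setdiff(cal$name, names(by_analyte))
  if (length(absent)) {
    stop("calibrant(s) lacking ", if (config$mode == "multipass") "t_pp"
         else "t_p1", " measurements (no traces present): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ext <- lapply(cal$name, function(nm) analyte_drift(by_analyte[[nm]], config))
  cal$drift <- vapply(ext, `[[`, numeric(1), "drift")
  curve <- build_curve(cal, mode = config$mode, gas_mass = config$gas_mass,
                       dead_time = config$dead_time)
  curve$models <- data.frame(
    analyte = cal$name,
    t_pp = vapply(ext, function(e)
      if (is.null(e$model)) NA_real_ else e$model$t_pp, numeric(1)),
    intercept = vapply(ext, function(e)
      if (is.null(e$model)) NA_real_ else e$model$intercept, numeric(1)),
    r_squared = vapply(ext, function(e)
      if (is.null(e$model)) NA_real_ else e$model$r_squared, numeric(1)),
    n_points = vapply(ext, function(e)
      if (is.null(e$model)) NA_integer_ else e$model$n_points, integer(1)),
    bypass = vapply(ext, `[[`, numeric(1), "bypass"),
    t_p1 = vapply(ext, `[[`, numeric(1), "t_p1"),
    stringsAsFactors = FALSE)
  curve
}

#' Calculate CCS values for analytes
#'
#' Processing driver: extracts each analyte's drift value (t_pp or t_p1,
#' matching the curve's mode) from its traces and predicts CCS from the
#' calibration curve, optionally comparing against reference values.
#'
#' @param traces Named list of [atd_trace]; each analyte needs the same
#'   acquisition structure as in [calibrate_traces]. Traces must carry
#'   `mz` and `charge` (or supply them via `references`).
#' @param curve A `ccs_calibration`, e.g. from [calibrate_traces] or
#'   [load_curve].
#' @param references Optional data.frame (`name`, `ccs`, optionally `mz`,
#'   `charge`) of known/predicted CCS values for comparison.
#' @param config A [ccs_config]; its `mode` must match the curve's.
#' @return Data.frame with one row per analyte, in trace order:
#'   `analyte_id`, `mode`, `drift_value`, `mz`, `charge`, `reduced_mass`,
#'   `ccs`, `extrapolated`, diagnostics (`model_r_squared`, `n_points`,
#'   `n_excluded`, `flags`) and, when references are given,
#'   `ccs_reference` and `percent_difference`.
#' @export
process_traces <- function(traces, curve, references = NULL,
                           config = ccs_config()) {
  stopifnot(inherits(curve, "ccs_calibration"),
            inherits(config, "ccs_config"))
  if (!identical(config$mode, curve$mode)) {
    stop("mode mismatch: config requests '", config$mode,
         "' but the calibration curve was built in '", curve$mode,
         "' mode", call. = FALSE)
  }
  by_analyte <- split_traces_by_analyte(traces)
  ref <- if (!is.null(references)) as.data.frame(references)
  rows <- lapply(names(by_analyte), function(nm) {
    e <- analyte_drift(by_analyte[[nm]], config)
    mz <- e$mz; charge <- e$charge
    if ((is.na(mz) || is.na(charge)) && !is.null(ref) &&
        all(c("mz", "charge") %in% names(ref)) && nm %in% ref$name) {
      i <- match(nm, ref$name)
      if (is.na(mz)) mz <- ref$mz[i]
      if (is.na(charge)) charge <- ref$charge[i]
    }
    if (is.na(mz) || is.na(charge)) {
      stop("analyte '", nm, "': m/z and charge are required to compute ",
           "CCS; supply them in the trace data or the references table",
           call. = FALSE)
    }
    ccs_ref <- NA_real_
    if (!is.null(ref) && nm %in% ref$name) {
      ref_col <- intersect(c("ccs", "ccs_ref"), names(ref))[1]
      if (!is.na(ref_col)) ccs_ref <- ref[[ref_col]][match(nm, ref$name)]
    }
    out <- predict_ccs(curve, drift = e$drift, mz = mz, charge = charge,
                       analyte_id = nm, ccs_reference = ccs_ref,
                       extrapolation_factor = config$extrapolation_factor)
    out$model_r_squared <- if (is.null(e$model)) NA_real_
                           else e$model$r_squared
    out$n_points <- if (is.null(e$model)) NA_integer_ else e$model$n_points
    out$n_excluded <- if (is.null(e$series)) 0L else sum(e$series$excluded)
    out$flags <- if (is.null(e$series)) "" else
      paste(unique(c(e$series$reason[e$series$excluded],
                     e$series$flag[nzchar(e$series$flag)])),
            collapse = ";")
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
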