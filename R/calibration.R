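## Traveling-wave CCS calibration.
##
## TWIMS instruments do not yield CCS from first principles; a power law
## is fitted between drift time and reference CCS values of calibrant
## standards, after removing the trivial mass and charge dependence:
##   omega' = omega * sqrt(mu) / z,   mu = m_ion * m_gas / (m_ion + m_gas)
##   omega' = A * t^B
## Unknowns are then assigned CCS by inverting the scaling at their own
## m/z and charge. The same machinery serves single-pass calibration
## (drift value = t_p1) and multipass calibration (drift value = t_pp).

#' Reduced mass of an ion-gas pair
#'
#' `mu = m_ion * m_gas / (m_ion + m_gas)`, in Da.
#'
#' @param ion_mass Ion mass in Da (> 0). For an adducted ion this is the
#'   full adduct mass, i.e. `mz * charge` (electron mass neglected).
#' @param gas_mass Buffer gas mass in Da; default nitrogen, 28.0134 Da.
#' @return Reduced mass in Da.
#' @export
reduced_mass <- function(ion_mass, gas_mass = 28.0134) {
  if (any(!is.finite(ion_mass) | ion_mass <= 0) ||
      any(!is.finite(gas_mass) | gas_mass <= 0)) {
    stop("masses must be positive and finite", call. = FALSE)
  }
  ion_mass * gas_mass / (ion_mass + gas_mass)
}

#' Scale a CCS for traveling-wave calibration
#'
#' `scale_ccs` maps a CCS to the calibration ordinate
#' `omega' = omega * sqrt(mu) / z`; `unscale_ccs` is its exact inverse.
#'
#' @param ccs CCS in squared Angstroms (> 0).
#' @param charge Integer charge state (>= 1).
#' @param mu Reduced mass in Da (see [reduced_mass]).
#' @return Scaled CCS (`scale_ccs`) or CCS in squared Angstroms
#'   (`unscale_ccs`).
#' @export
scale_ccs <- function(ccs, charge, mu) {
  if (any(charge == 0)) stop("charge must be nonzero", call. = FALSE)
  if (any(mu <= 0)) stop("reduced mass must be > 0", call. = FALSE)
  ccs * sqrt(mu) / charge
}

#' @rdname scale_ccs
#' @param scaled Scaled CCS value.
#' @export
unscale_ccs <- function(scaled, charge, mu) {
  if (any(charge == 0)) stop("charge must be nonzero", call. = FALSE)
  if (any(mu <= 0)) stop("reduced mass must be > 0", call. = FALSE)
  scaled * charge / sqrt(mu)
}

#' Fit a power law between drift time and scaled CCS
#'
#' Linear least squares in log-log space: `ln(omega') = ln(A) + B ln(t)`,
#' so `A = exp(intercept)` and `B = slope`. R-squared is reported in log
#' space, where the fit is performed.
#'
#' @param drift Drift values in ms (> 0); t_p1 or t_pp depending on mode.
#' @param scaled_ccs Scaled CCS values (> 0), same length.
#' @return List with `A`, `B`, `r_squared`, and the underlying `lm` fit.
#' @export
fit_power_law <- function(drift, scaled_ccs) {
  if (length(drift) != length(scaled_ccs)) {
    stop("drift and scaled_ccs must have equal length", call. = FALSE)
  }
  if (length(drift) < 3L) {
    stop("insufficient calibrants: at least 3 (drift, CCS) pairs are ",
         "required, got ", length(drift), call. = FALSE)
  }
  if (any(drift <= 0) || any(scaled_ccs <= 0)) {
    stop("drift and scaled CCS values must be positive", call. = FALSE)
  }
  df <- data.frame(lx = log(drift), ly = log(scaled_ccs))
  fit <- stats::lm(ly ~ lx, data = df)
  cf <- stats::coef(fit)
  ss_tot <- sum((df$ly - mean(df$ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(A = unname(exp(cf["(Intercept)"])), B = unname(cf["lx"]),
       r_squared = r2, fit = fit)
}

new_ccs_calibration <- function(A, B, mode, gas_mass, fit_r_squared,
                                drift_range, calibrant_table, created_with,
                                fit = NULL) {
  structure(list(A = A, B = B, mode = mode, gas_mass = gas_mass,
                 fit_r_squared = fit_r_squared, drift_range = drift_range,
                 calibrant_table = calibrant_table,
                 created_with = created_with, fit = fit),
            class = "ccs_calibration")
}

#' Build a CCS calibration curve
#'
#' Compiles measured drift values (t_p1 for single-pass mode, t_pp for
#' multipass mode) and reference CCS values across calibrants, applies the
#' reduced-mass/charge scaling, and fits the power law. The per-calibrant
#' table is retained on the object for audit.
#'
#' @param calibrants Data.frame with columns `name`, `mz`, `charge`,
#'   `ccs_ref` (e.g. from [read_calibrant_list]) plus a drift-value
#'   column: `drift`, or `t_pp`/`t_p1` matching `mode`.
#' @param mode `"multipass"` (calibrate against t_pp) or `"single-pass"`
#'   (against t_p1).
#' @param gas_mass Buffer gas mass in Da (default nitrogen).
#' @param dead_time Constant subtracted from every drift value before
#'   fitting, ms (default 0; the bypass subtraction upstream already
#'   absorbs fixed transit offsets).
#' @return A `ccs_calibration` object with fields `A`, `B`, `mode`,
#'   `gas_mass`, `fit_r_squared`, `drift_range`, `calibrant_table`.
#' @export
#' @seealso [predict.ccs_calibration], [persist_curve]
build_curve <- function(calibrants, mode = c("multipass", "single-pass"),
                        gas_mass = 28.0134, dead_time = 0) {
  mode <- match.arg(mode)
  df <- as.data.frame(calibrants)
  need <- c("name", "mz", "charge", "ccs_ref")
  if (!all(need %in% names(df))) {
    stop("calibrants must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  drift_col <- if ("drift" %in% names(df)) "drift"
               else if (mode == "multipass") "t_pp" else "t_p1"
  if (!drift_col %in% names(df)) {
    stop("mode '", mode, "' requires a '", drift_col, "' (or 'drift') ",
         "column on the calibrant table", call. = FALSE)
  }
  missing_drift <- which(!is.finite(df[[drift_col]]))
  if (length(missing_drift)) {
    stop("calibrant(s) lacking a ", drift_col, " value: ",
         paste(df$name[missing_drift], collapse = ", "), call. = FALSE)
  }
  drift <- df[[drift_col]] - dead_time
  if (any(drift <= 0)) {
    stop("non-positive drift value after dead-time subtraction",
         call. = FALSE)
  }
  mu <- reduced_mass(df$mz * df$charge, gas_mass)
  scaled <- scale_ccs(df$ccs_ref, df$charge, mu)
  pl <- fit_power_law(drift, scaled)
  tab <- data.frame(name = df$name, mz = df$mz, charge = df$charge,
                    drift = drift, ccs_ref = df$ccs_ref,
                    reduced_mass = mu, scaled_ccs = scaled,
                    fitted_scaled = pl$A * drift^pl$B,
                    stringsAsFactors = FALSE)
  new_ccs_calibration(
    A = pl$A, B = pl$B, mode = mode, gas_mass = gas_mass,
    fit_r_squared = pl$r_squared, drift_range = range(drift),
    calibrant_table = tab,
    created_with = list(dead_time = dead_time,
                        n_calibrants = nrow(df),
                        package_version = as.character(
                          utils::packageVersion("cimscal"))),
    fit = pl$fit)
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat(sprintf("CCS calibration curve (%s mode)\n", x$mode))
  cat(sprintf("  omega' = %.6g * t^%.6f   (R^2 = %.8f in log space)\n",
              x$A, x$B, x$fit_r_squared))
  cat(sprintf("  %d calibrants, drift range [%.4g, %.4g] ms, gas %.4f Da\n",
              nrow(x$calibrant_table), x$drift_range[1], x$drift_range[2],
              x$gas_mass))
  invisible(x)
}

#' @export
coef.ccs_calibration <- function(object, ...) {
  c(A = object$A, B = object$B)
}

#' @export
summary.ccs_calibration <- function(object, ...) {
  print(object)
  tab <- object$calibrant_table
  back <- unscale_ccs(tab$fitted_scaled, tab$charge, tab$reduced_mass)
  tab$ccs_back <- back
  tab$pct_resid <- 100 * (back - tab$ccs_ref) / tab$ccs_ref
  cat("\nCalibrant residuals (CCS space):\n")
  print(tab[, c("name", "drift", "ccs_ref", "ccs_back", "pct_resid")],
        digits = 6, row.names = FALSE)
  invisible(tab)
}

#' Predict CCS for analytes from a calibration curve
#'
#' Applies the power law at each analyte's drift value and undoes the
#' reduced-mass/charge scaling:
#' `CCS = A * t^B * z / sqrt(mu)` with `mu = reduced_mass(mz * z, gas)`.
#' Drift values outside the calibrant range by more than the extrapolation
#' factor trigger a warning and are flagged in the result.
#'
#' @param object A `ccs_calibration`.
#' @param newdata Data.frame with columns `drift` (ms), `mz`, `charge` and
#'   optionally `analyte_id`, `ccs_reference`.
#' @param extrapolation_factor Allowed multiplicative excursion beyond the
#'   calibrant drift range before the extrapolation flag is raised
#'   (default 1.5).
#' @param ... Unused.
#' @return Data.frame with one row per analyte: `analyte_id`, `mode`,
#'   `drift_value`, `mz`, `charge`, `reduced_mass`, `ccs`, and when a
#'   reference is given `ccs_reference` and `percent_difference`; plus a
#'   logical `extrapolated` column.
#' @export
predict.ccs_calibration <- function(object, newdata,
                                    extrapolation_factor = 1.5, ...) {
  df <- as.data.frame(newdata)
  if (!all(c("drift", "mz", "charge") %in% names(df))) {
    stop("newdata must have columns drift, mz, charge", call. = FALSE)
  }
  if (any(df$drift <= 0)) stop("drift values must be > 0", call. = FALSE)
  mu <- reduced_mass(df$mz * df$charge, object$gas_mass)
  scaled <- object$A * df$drift^object$B
  ccs <- unscale_ccs(scaled, df$charge, mu)
  lo <- object$drift_range[1] / extrapolation_factor
  hi <- object$drift_range[2] * extrapolation_factor
  extrap <- df$drift < lo | df$drift > hi
  if (any(extrap)) {
    warning(sum(extrap), " drift value(s) lie beyond ", extrapolation_factor,
            "x the calibrant drift range [",
            signif(object$drift_range[1], 5), ", ",
            signif(object$drift_range[2], 5),
            "] ms; CCS extrapolated", call. = FALSE)
  }
  out <- data.frame(
    analyte_id = if ("analyte_id" %in% names(df)) df$analyte_id
                 else sprintf("analyte_%d", seq_len(nrow(df))),
    mode = object$mode, drift_value = df$drift, mz = df$mz,
    charge = df$charge, reduced_mass = mu, ccs = ccs,
    extrapolated = extrap, stringsAsFactors = FALSE)
  if ("ccs_reference" %in% names(df) && any(is.finite(df$ccs_reference))) {
    out$ccs_reference <- df$ccs_reference
    out$percent_difference <- ifelse(
      is.finite(df$ccs_reference),
      percent_difference(df$ccs_reference, ccs), NA_real_)
  }
  out
}

#' Predict a single CCS value
#'
#' Convenience scalar wrapper around [predict.ccs_calibration].
#'
#' @inheritParams predict.ccs_calibration
#' @param curve A `ccs_calibration`.
#' @param drift Drift value in ms (t_p1 or t_pp per the curve's mode).
#' @param mz,charge Ion m/z (Th) and charge state.
#' @param analyte_id Optional label.
#' @param ccs_reference Optional reference CCS for percent-difference
#'   reporting.
#' @return One-row data.frame as in [predict.ccs_calibration].
#' @export
predict_ccs <- function(curve, drift, mz, charge, analyte_id = "analyte",
                        ccs_reference = NA_real_,
                        extrapolation_factor = 1.5) {
  predict(curve,
          data.frame(analyte_id = analyte_id, drift = drift, mz = mz,
                     charge = charge, ccs_reference = ccs_reference),
          extrapolation_factor = extrapolation_factor)
}

#' @export
plot.ccs_calibration <- function(x, ...) {
  tab <- x$calibrant_table
  tt <- seq(min(tab$drift), max(tab$drift), length.out = 200)
  plot(tab$drift, tab$scaled_ccs, xlab = "drift value (ms)",
       ylab = expression("scaled CCS " * Omega * minute),
       main = sprintf("%s calibration: A = %.4g, B = %.4f", x$mode,
                      x$A, x$B), ...)
  graphics::lines(tt, x$A * tt^x$B, col = "red")
  invisible(x)
}

#' Percent difference between a measured and a reference CCS
#'
#' `100 * |measured - reference| / reference`, reported to two decimal
#' places (the convention used for cross-workflow CCS comparisons).
#'
#' @param reference Reference CCS (> 0), the denominator.
#' @param measured Measured CCS.
#' @return Percent difference, rounded to 2 decimals (vectorized).
#' @export
#' @examples
#' percent_difference(280.1, 279.2)  # 0.32
percent_difference <- function(reference, measured) {
  if (any(reference <= 0)) stop("reference CCS must be > 0", call. = FALSE)
  round(100 * abs(measured - reference) / reference, 2)
}
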