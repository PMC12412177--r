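## Multipass drift-time analysis.
##
## Traveling-wave field switching at ion ejection perturbs measured arrival
## times, so a single multipass arrival time is not proportional to the
## number of passes n. The correction regresses total drift time
## t_nd = t_n - bypass on n over several separation times; the slope is the
## perturbation-corrected periodic drift time t_pp (ms per pass).

#' Measure the bypass time
#'
#' The bypass time is the arrival time recorded when ions effectively skip
#' the cyclic separation (conventionally at t_s = 0.01 ms); it is
#' subtracted from every multipass arrival time to form the total drift
#' time. The value is the Gaussian-fitted center of the primary peak.
#'
#' @param trace An [atd_trace] acquired at the bypass setting.
#' @param bypass_ts Nominal bypass separation time in ms (default 0.01).
#' @param strict If `TRUE`, a trace whose separation time is outside
#'   `tol` is an error; if `FALSE` (lenient, default) traces with t_s in
#'   `tol` are accepted with no complaint and anything else is an error.
#' @param tol Accepted separation-time interval (ms) for a bypass trace.
#' @return Bypass time in ms (Gaussian center).
#' @export
measure_bypass <- function(trace, bypass_ts = 0.01, strict = FALSE,
                           tol = c(0.005, 0.05)) {
  stopifnot(inherits(trace, "atd_trace"))
  ts <- trace$separation_time
  ok <- if (strict) isTRUE(all.equal(ts, bypass_ts, tolerance = 1e-6))
        else ts >= tol[1] && ts <= tol[2]
  if (!ok) {
    stop("trace '", trace$analyte_id, "' has t_s = ", ts,
         " ms; not a bypass acquisition (expected ~", bypass_ts, " ms)",
         call. = FALSE)
  }
  fit_gaussian(trace, window = pick_primary_peak(trace))$center
}

#' Automated pass counting
#'
#' Estimates the number of passes n completed around the cyclic cell from
#' a measured arrival time, the single-pass arrival time and the bypass
#' time: `n = round((t_n - bypass) / (t_p1 - bypass))`. A ratio whose
#' fractional part falls within 0.25 of a half-integer triggers an
#' ambiguity warning (the assignment is then sensitive to drift-time
#' error).
#'
#' @param t_n Measured arrival time(s), ms (vectorized).
#' @param t_p1 Single-pass arrival time, ms; must exceed `bypass`.
#' @param bypass Bypass time, ms.
#' @return Integer vector of pass counts (>= 0), with attribute
#'   `ambiguous`: logical vector marking near-half-integer ratios.
#' @export
#' @examples
#' count_passes(105, t_p1 = 25, bypass = 5)  # 5 passes
count_passes <- function(t_n, t_p1, bypass) {
  if (!is.finite(t_p1) || !is.finite(bypass) || t_p1 <= bypass) {
    stop("invalid reference times: t_p1 (", t_p1,
         ") must exceed the bypass time (", bypass, ")", call. = FALSE)
  }
  if (any(t_n < bypass)) {
    stop("arrival time earlier than the bypass time", call. = FALSE)
  }
  ratio <- (t_n - bypass) / (t_p1 - bypass)
  n <- as.integer(floor(ratio + 0.5))  # nearest integer, ties round up
  ambiguous <- abs(ratio - floor(ratio) - 0.5) < 0.25
  if (any(ambiguous)) {
    warning("ambiguous pass count: ratio(s) ",
            paste(sprintf("%.3f", ratio[ambiguous]), collapse = ", "),
            " lie near a half-integer", call. = FALSE)
  }
  structure(n, ambiguous = ambiguous)
}

#' Build the separation-time series for one analyte
#'
#' Converts a set of ATD traces of one analyte, acquired at several
#' separation times, into the points of the perturbation-correction linear
#' model. For each trace the arrival time t_n is the primary-peak Gaussian
#' center, the pass count n comes from [count_passes], and the total drift
#' time is `t_nd = t_n - bypass`.
#'
#' Traces whose ATD is split into well-separated modes (wrap-around
#' artifact not reconstructed upstream) are flagged excluded with reason
#' `"wraparound"`. If the largest included pass count is below
#' `min_passes`, a warning is emitted and the offending points carry a
#' `below_min_passes` flag (they stay included; the minimum-pass rule is a
#' data-quality advisory for analytes, not a hard filter).
#'
#' @param traces List of [atd_trace] for one analyte.
#' @param bypass Bypass time, ms (see [measure_bypass]).
#' @param t_p1 Single-pass arrival time, ms.
#' @param min_passes Advisory minimum pass count per point (default 4).
#' @param width_mult Passed to [pick_primary_peak].
#' @return A `separation_series` data.frame with columns
#'   `separation_time`, `arrival_time`, `n_passes`, `total_drift`,
#'   `excluded`, `reason`, `flag`, `fit_r_squared`; attribute `analyte`.
#' @export
build_separation_series <- function(traces, bypass, t_p1, min_passes = 4L,
                                    width_mult = 6) {
  if (inherits(traces, "atd_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  ids <- unique(vapply(traces, `[[`, character(1), "analyte_id"))
  if (length(ids) != 1L) {
    stop("all traces must belong to one analyte; got: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(traces, function(tr) {
    if (is_split_atd(tr)) {
      return(data.frame(separation_time = tr$separation_time,
                        arrival_time = NA_real_, n_passes = NA_integer_,
                        total_drift = NA_real_, excluded = TRUE,
                        reason = "wraparound", flag = "",
                        fit_r_squared = NA_real_))
    }
    fit <- fit_gaussian(tr, window = pick_primary_peak(tr, width_mult))
    n <- suppressWarnings(count_passes(fit$center, t_p1, bypass))
    data.frame(separation_time = tr$separation_time,
               arrival_time = fit$center, n_passes = as.integer(n),
               total_drift = fit$center - bypass,
               excluded = FALSE,
               reason = "",
               flag = if (attr(n, "ambiguous")) "ambiguous_pass_count" else "",
               fit_r_squared = fit$r_squared)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$separation_time), , drop = FALSE]
  rownames(out) <- NULL
  incl <- !out$excluded
  # sanity-check: pass counts should not decrease with separation time
  if (any(diff(out$n_passes[incl]) < 0)) {
    warning("pass counts are not monotone in separation time for '",
            ids, "'; check t_p1/bypass references", call. = FALSE)
  }
  low <- incl & out$n_passes < min_passes
  if (any(incl) && max(out$n_passes[incl]) < min_passes) {
    warning("analyte '", ids, "': at most ", max(out$n_passes[incl]),
            " passes observed; a minimum of ", min_passes,
            " passes per calibrant is recommended", call. = FALSE)
  }
  out$flag[low] <- trimws(paste(out$flag[low], "below_min_passes"))
  attr(out, "analyte") <- ids
  class(out) <- c("separation_series", "data.frame")
  out
}

## Heuristic wrap-around detector: two well-separated smoothed maxima,
## both prominent, with a deep valley between them.
is_split_atd <- function(trace) {
  y <- smooth_intensity(trace$intensities)
  n <- length(y)
  is_max <- c(y[1L] > y[2L],
              y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n],
              y[n] > y[n - 1L])  # a wrapped apex can sit on a span edge
  apex <- which(is_max & y > 0.3 * max(y))
  if (length(apex) < 2L) return(FALSE)
  apex <- apex[order(-y[apex])][1:2]
  if (abs(diff(apex)) < 5L) return(FALSE)
  valley <- min(y[min(apex):max(apex)])
  valley < 0.5 * min(y[apex])
}

#' Fit the perturbation-correction linear model
#'
#' Ordinary least squares of total drift time t_nd on pass count n over
#' the included points of a [build_separation_series] result. The slope is
#' the perturbation-corrected periodic drift time t_pp (ms per pass): the
#' per-pass drift time with the constant arrival-time perturbation from
#' electric-field switching absorbed into the intercept.
#'
#' @param points A `separation_series` data.frame (or any data.frame with
#'   columns `n_passes`, `total_drift` and optionally `excluded`).
#' @param min_points Minimum number of included points (default 6).
#' @param bypass,t_p1 Optional reference times stored on the model for
#'   audit.
#' @return A `perturbation_model`: fields `t_pp`, `intercept`,
#'   `r_squared`, `n_points`, `bypass_time`, `t_p1`, `points`, and the
#'   underlying `lm` fit.
#' @export
#' @examples
#' pts <- data.frame(n_passes = 4:9, total_drift = c(4:9) * 20)
#' fit_perturbation_model(pts)  # slope exactly 20, intercept 0
fit_perturbation_model <- function(points, min_points = 6L,
                                   bypass = NA_real_, t_p1 = NA_real_) {
  analyte <- attr(points, "analyte")
  if (is.null(analyte)) analyte <- "<unnamed>"
  df <- as.data.frame(points)
  if (!all(c("n_passes", "total_drift") %in% names(df))) {
    stop("points must have columns n_passes and total_drift", call. = FALSE)
  }
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  incl <- df[!df$excluded & is.finite(df$total_drift), , drop = FALSE]
  if (nrow(incl) < min_points) {
    stop("analyte '", analyte, "': only ", nrow(incl),
         " included data point(s); at least ", min_points,
         " data points per calibrant are required for the ",
         "perturbation-corrected drift time", call. = FALSE)
  }
  if (length(unique(incl$n_passes)) < 2L) {
    stop("analyte '", analyte, "': all points share one pass count; ",
         "the linear model is rank-deficient", call. = FALSE)
  }
  fit <- stats::lm(total_drift ~ n_passes, data = incl)
  cf <- stats::coef(fit)
  ss_tot <- sum((incl$total_drift - mean(incl$total_drift))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(t_pp = unname(cf["n_passes"]), intercept = unname(cf["(Intercept)"]),
         r_squared = r2, n_points = nrow(incl),
         bypass_time = bypass, t_p1 = t_p1, analyte = analyte,
         points = df, fit = fit),
    class = "perturbation_model")
}

#' @export
print.perturbation_model <- function(x, ...) {
  cat("Perturbation-corrected drift time model for '", x$analyte, "'\n",
      sep = "")
  cat(sprintf("  t_pp = %.6f ms/pass, intercept = %.6f ms\n",
              x$t_pp, x$intercept))
  cat(sprintf("  R^2 = %.8f over %d points\n", x$r_squared, x$n_points))
  excl <- sum(x$points$excluded)
  if (excl > 0) cat("  ", excl, "point(s) excluded (",
                    paste(unique(x$points$reason[x$points$excluded]),
                          collapse = ", "), ")\n")
  invisible(x)
}

#' @export
coef.perturbation_model <- function(object, ...) {
  c(intercept = object$intercept, t_pp = object$t_pp)
}

#' @export
summary.perturbation_model <- function(object, ...) {
  s <- summary(object$fit)
  cat(sprintf("t_pp = %.6f +/- %.6f ms/pass (R^2 = %.8f, n = %d)\n",
              object$t_pp, s$coefficients["n_passes", "Std. Error"],
              object$r_squared, object$n_points))
  invisible(s)
}

#' @export
predict.perturbation_model <- function(object, n_passes, ...) {
  object$intercept + object$t_pp * n_passes
}

#' @export
residuals.perturbation_model <- function(object, ...) {
  stats::residuals(object$fit)
}

#' @export
plot.perturbation_model <- function(x, ...) {
  df <- x$points[!x$points$excluded, ]
  plot(df$n_passes, df$total_drift, xlab = "passes (n)",
       ylab = expression(t[nd] ~ "(ms)"),
       main = sprintf("%s: t_pp = %.4f ms/pass", x$analyte, x$t_pp), ...)
  graphics::abline(x$intercept, x$t_pp, col = "red")
  invisible(x)
}
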