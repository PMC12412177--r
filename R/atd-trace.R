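#' Arrival time distribution trace
#'
#' Container for one arrival time distribution (ATD): the intensity profile
#' of a single ion species recorded at one cyclic-IMS separation time.
#' All drift/arrival times are in milliseconds, intensities in detector
#' counts.
#'
#' @param analyte_id Character label for the ion species.
#' @param separation_time Applied separation time t_s in ms (> 0). The
#'   bypass acquisition is conventionally recorded at t_s = 0.01 ms.
#' @param times Numeric vector of drift times in ms, strictly increasing,
#'   length >= 5.
#' @param intensities Numeric vector of non-negative intensities, same
#'   length as `times`.
#' @param mz Mass-to-charge of the ion in Th (optional, `NA` if unknown).
#' @param charge Positive integer charge state (optional).
#'
#' @return An object of class `atd_trace`.
#' @export
#' @examples
#' t <- seq(20, 30, by = 0.05)
#' y <- 1000 * exp(-(t - 25)^2 / (2 * 0.5^2))
#' tr <- atd_trace("leuenk", 100, t, y, mz = 556.2771, charge = 1)
#' print(tr)
atd_trace <- function(analyte_id, separation_time, times, intensities,
                      mz = NA_real_, charge = NA_integer_) {
  obj <- structure(
    list(
      analyte_id = as.character(analyte_id),
      mz = as.numeric(mz),
      charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
      separation_time = as.numeric(separation_time),
      times = as.numeric(times),
      intensities = as.numeric(intensities)
    ),
    class = "atd_trace"
  )
  validate_atd_trace(obj)
}

#' Validate an ATD trace
#'
#' Checks the `atd_trace` invariants: strictly increasing times, matched
#' vector lengths (>= 5 points), positive separation time, non-negative
#' intensities.
#'
#' @param x An `atd_trace`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_atd_trace <- function(x) {
  stopifnot(inherits(x, "atd_trace"))
  if (length(x$times) != length(x$intensities)) {
    stop("atd_trace '", x$analyte_id,
         "': times and intensities differ in length", call. = FALSE)
  }
  if (length(x$times) < 5L) {
    stop("atd_trace '", x$analyte_id, "': at least 5 points are required",
         call. = FALSE)
  }
  if (anyNA(x$times) || any(diff(x$times) <= 0)) {
    stop("atd_trace '", x$analyte_id, "': times must be strictly increasing",
         call. = FALSE)
  }
  if (anyNA(x$intensities) || any(x$intensities < 0)) {
    stop("atd_trace '", x$analyte_id,
         "': intensities must be non-negative", call. = FALSE)
  }
  if (!is.finite(x$separation_time) || x$separation_time <= 0) {
    stop("atd_trace '", x$analyte_id, "': separation_time must be > 0",
         call. = FALSE)
  }
  if (!is.na(x$charge) && x$charge < 1L) {
    stop("atd_trace '", x$analyte_id, "': charge must be >= 1", call. = FALSE)
  }
  x
}

#' @export
print.atd_trace <- function(x, ...) {
  cat("ATD trace '", x$analyte_id, "'\n", sep = "")
  cat(sprintf("  t_s = %g ms, %d points over [%.3f, %.3f] ms\n",
              x$separation_time, length(x$times),
              min(x$times), max(x$times)))
  if (!is.na(x$mz)) {
    cat(sprintf("  m/z %.4f, charge %s\n", x$mz,
                ifelse(is.na(x$charge), "?", x$charge)))
  }
  cat(sprintf("  max intensity %.4g at %.3f ms\n",
              max(x$intensities), x$times[which.max(x$intensities)]))
  invisible(x)
}

#' @export
plot.atd_trace <- function(x, fit = NULL, main = NULL, ...) {
  if (is.null(main)) {
    main <- sprintf("%s (t_s = %g ms)", x$analyte_id, x$separation_time)
  }
  plot(x$times, x$intensities, type = "l", xlab = "drift time (ms)",
       ylab = "intensity", main = main, ...)
  if (!is.null(fit)) {
    tt <- seq(min(x$times), max(x$times), length.out = 400)
    graphics::lines(tt, predict(fit, newtimes = tt), col = "red", lwd = 2)
  }
  invisible(x)
}

## internal: subset a trace to a time window, preserving metadata
window_trace <- function(trace, window) {
  keep <- trace$times >= window[1] & trace$times <= window[2]
  if (!any(keep)) {
    stop("window [", window[1], ", ", window[2],
         "] excludes all points of trace '", trace$analyte_id, "'",
         call. = FALSE)
  }
  list(times = trace$times[keep], intensities = trace$intensities[keep])
}
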