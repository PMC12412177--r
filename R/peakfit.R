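## Gaussian peak extraction from arrival time distributions.
##
## The arrival time t_n of an ion at a given separation time is taken as
## the center of a Gaussian fitted to the ATD by nonlinear least squares
## (Levenberg-Marquardt, via minpack.lm). Multi-component fits share a
## constant baseline.

gauss_model <- function(times, amp, cen, sig, base) {
  y <- rep(base, length(times))
  for (j in seq_along(amp)) {
    y <- y + amp[j] * exp(-(times - cen[j])^2 / (2 * sig[j]^2))
  }
  y
}

## FWHM of the peak at index `apex` by linear interpolation at half height,
## measured above the trace minimum. Falls back to mirroring one side, then
## to a fraction of the span, when a crossing is missing (edge peaks).
estimate_fwhm <- function(times, y, apex) {
  base <- min(y)
  half <- base + (y[apex] - base) / 2
  left <- NA_real_
  for (i in seq(apex, 2L)) {
    if (y[i - 1L] < half && y[i] >= half) {
      left <- times[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) *
        (times[i] - times[i - 1L])
      break
    }
  }
  right <- NA_real_
  if (apex < length(y)) {
    for (i in seq(apex, length(y) - 1L)) {
      if (y[i] >= half && y[i + 1L] < half) {
        right <- times[i] + (y[i] - half) / (y[i] - y[i + 1L]) *
          (times[i + 1L] - times[i])
        break
      }
    }
  }
  if (is.na(left) && is.na(right)) return(diff(range(times)) / 4)
  if (is.na(left)) return(2 * (right - times[apex]))
  if (is.na(right)) return(2 * (times[apex] - left))
  right - left
}

## k highest local maxima, pairwise separated by >= min_sep grid steps;
## ties broken toward earlier time. Plateaus count once, at their first
## point. Pads with intensity quantile positions if too few maxima exist.
find_peak_candidates <- function(times, y, k, min_sep = 3L) {
  n <- length(y)
  is_max <- logical(n)
  for (i in 2:(n - 1L)) {
    if (y[i] > y[i - 1L] && y[i] >= y[i + 1L]) is_max[i] <- TRUE
  }
  if (y[1L] > y[2L]) is_max[1L] <- TRUE
  if (y[n] > y[n - 1L]) is_max[n] <- TRUE
  cand <- which(is_max)
  cand <- cand[order(-y[cand], cand)]  # intensity desc, earlier time wins
  picked <- integer(0)
  for (i in cand) {
    if (all(abs(i - picked) >= min_sep)) picked <- c(picked, i)
    if (length(picked) == k) break
  }
  if (length(picked) < k) {
    extra <- round(seq(1L, n, length.out = k + 2L))[2:(k + 1L)]
    extra <- setdiff(extra, picked)
    picked <- c(picked, extra)[seq_len(k)]
  }
  picked
}

fit_gaussian_core <- function(times, y, k, baseline = TRUE,
                              max_iter = 500L, ftol = 1e-10) {
  n <- length(y)
  if (n < 3L * k + 2L) {
    stop("need at least ", 3L * k + 2L, " points to fit ", k,
         " Gaussian component(s), got ", n, call. = FALSE)
  }
  if (diff(range(y)) == 0) {
    stop("flat trace: all intensities equal; cannot fit a Gaussian",
         call. = FALSE)
  }
  span <- range(times)
  step <- min(diff(times))
  # initialize from a lightly smoothed profile so detector-noise spikes do
  # not masquerade as components; the fit itself uses the raw data
  ys <- if (k > 1L) smooth_intensity(y) else y
  apex <- find_peak_candidates(times, ys, k)
  base0 <- if (baseline) min(y) else 0
  amp0 <- pmax(y[apex] - base0, diff(range(y)) * 1e-3)
  sig0 <- vapply(apex, function(i)
    max(estimate_fwhm(times, ys, i) / 2.3548, step), numeric(1))
  par0 <- c(amp0, times[apex], sig0, if (baseline) base0)
  lower <- c(rep(0, k), rep(span[1], k), rep(step / 10, k),
             if (baseline) -Inf)
  upper <- c(rep(Inf, k), rep(span[2], k), rep(diff(span), k),
             if (baseline) Inf)
  resid_fn <- function(p) {
    amp <- p[1:k]; cen <- p[(k + 1):(2 * k)]; sig <- p[(2 * k + 1):(3 * k)]
    base <- if (baseline) p[3 * k + 1] else 0
    gauss_model(times, amp, cen, sig, base) - y
  }
  res <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = ftol, ptol = 1e-12, gtol = 0))
  p <- res$par
  converged <- res$info %in% c(1L, 2L, 3L, 4L) && res$niter < max_iter
  fitted <- gauss_model(times, p[1:k], p[(k + 1):(2 * k)],
                        p[(2 * k + 1):(3 * k)],
                        if (baseline) p[3 * k + 1] else 0)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  comps <- lapply(seq_len(k), function(j) {
    structure(list(amplitude = p[j], center = p[k + j], sigma = p[2 * k + j],
                   baseline = if (baseline) p[3 * k + 1] else 0,
                   r_squared = 1 - ss_res / ss_tot,
                   converged = converged,
                   window = span),
              class = "gaussian_fit")
  })
  comps[order(-vapply(comps, `[[`, numeric(1), "amplitude"))]
}

#' Fit a single Gaussian to an arrival time distribution
#'
#' Extracts the precise arrival time t_n of a mobility peak by nonlinear
#' least squares: the model is
#' `amplitude * exp(-(t - center)^2 / (2 * sigma^2)) + baseline`,
#' fitted with Levenberg-Marquardt under box constraints (center within the
#' time span, sigma positive and bounded by the span). The fitted `center`
#' is the reported arrival time.
#'
#' Initial values follow the usual moment heuristics: center at the
#' intensity maximum, amplitude = max - min, baseline = min, sigma from a
#' linear-interpolated FWHM at half height divided by 2.3548.
#'
#' @param trace An [atd_trace].
#' @param window Optional length-2 time interval (ms) restricting the fit,
#'   e.g. from [pick_primary_peak]. Default: the whole trace.
#' @param baseline Fit a constant baseline (default) or fix it to zero.
#' @param max_iter Iteration cap; the result is flagged `converged = FALSE`
#'   when it is hit.
#' @return A `gaussian_fit` object: fields `amplitude`, `center` (t_n, ms),
#'   `sigma` (ms), `baseline`, `r_squared`, `converged`.
#' @export
#' @examples
#' t <- seq(20, 30, by = 0.05)
#' tr <- atd_trace("pep", 100, t, 1000 * exp(-(t - 25)^2 / (2 * 0.25)))
#' fit_gaussian(tr)
fit_gaussian <- function(trace, window = NULL, baseline = TRUE,
                         max_iter = 500L) {
  stopifnot(inherits(trace, "atd_trace"))
  dat <- if (is.null(window)) {
    list(times = trace$times, intensities = trace$intensities)
  } else {
    window_trace(trace, window)
  }
  if (length(dat$times) < 5L) {
    stop("fit window holds fewer than 5 points", call. = FALSE)
  }
  fit_gaussian_core(dat$times, dat$intensities, k = 1L,
                    baseline = baseline, max_iter = max_iter)[[1]]
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian fit: center %.5f ms, sigma %.5f ms, amplitude %.4g,\n",
    x$center, x$sigma, x$amplitude))
  cat(sprintf("  baseline %.4g, R^2 = %.6f, %s\n", x$baseline, x$r_squared,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.gaussian_fit <- function(object, ...) {
  c(amplitude = object$amplitude, center = object$center,
    sigma = object$sigma, baseline = object$baseline)
}

#' @export
predict.gaussian_fit <- function(object, newtimes, ...) {
  gauss_model(newtimes, object$amplitude, object$center, object$sigma,
              object$baseline)
}

#' Window around the most intense ATD peak
#'
#' Returns the fit window used for primary-peak arrival time extraction: it
#' is centered on the global intensity maximum (ties broken toward earlier
#' time) with total width `width_mult` times a FWHM estimate at that
#' maximum, clipped to the trace span.
#'
#' @param trace An [atd_trace].
#' @param width_mult Window width as a multiple of the FWHM estimate
#'   (default 6).
#' @return Length-2 numeric time interval in ms.
#' @export
pick_primary_peak <- function(trace, width_mult = 6) {
  stopifnot(inherits(trace, "atd_trace"))
  y <- trace$intensities
  if (diff(range(y)) == 0) {
    stop("flat trace: no primary peak in '", trace$analyte_id, "'",
         call. = FALSE)
  }
  apex <- which(y == max(y))[1]  # earliest-time maximum on ties
  fwhm <- estimate_fwhm(trace$times, y, apex)
  half_width <- width_mult * fwhm / 2
  c(max(trace$times[apex] - half_width, min(trace$times)),
    min(trace$times[apex] + half_width, max(trace$times)))
}

#' Fit a sum of Gaussians to a multi-peak ATD
#'
#' Deconvolves partially resolved mobility features (e.g. isomer pairs) by
#' least-squares fitting of `k` Gaussian components plus one shared
#' constant baseline. Components are initialized at the `k` highest local
#' maxima (separated by at least 3 grid steps, earlier time wins ties) and
#' returned sorted by descending amplitude. Non-convergence is flagged on
#' the result rather than raised.
#'
#' @param trace An [atd_trace] with at least `3k + 2` points.
#' @param k Number of Gaussian components (>= 1), chosen by the user.
#' @inheritParams fit_gaussian
#' @return A `multi_gaussian_fit`: list with `components` (list of
#'   `gaussian_fit`, amplitude-descending), `k`, `r_squared`, `converged`.
#' @export
fit_multi_gaussian <- function(trace, k, baseline = TRUE, max_iter = 500L) {
  stopifnot(inherits(trace, "atd_trace"), k >= 1L)
  comps <- fit_gaussian_core(trace$times, trace$intensities, k = as.integer(k),
                             baseline = baseline, max_iter = max_iter)
  cen <- vapply(comps, `[[`, numeric(1), "center")
  if (anyDuplicated(signif(cen, 12))) {
    warning("multi-Gaussian fit collapsed two components onto one center",
            call. = FALSE)
  }
  structure(list(components = comps, k = as.integer(k),
                 r_squared = comps[[1]]$r_squared,
                 converged = comps[[1]]$converged),
            class = "multi_gaussian_fit")
}

#' @export
print.multi_gaussian_fit <- function(x, ...) {
  cat(sprintf("Multi-Gaussian fit, k = %d, R^2 = %.6f (%s)\n", x$k,
              x$r_squared,
              if (x$converged) "converged" else "NOT converged"))
  for (j in seq_len(x$k)) {
    cmp <- x$components[[j]]
    cat(sprintf("  [%d] center %.5f ms, sigma %.5f ms, amplitude %.4g\n",
                j, cmp$center, cmp$sigma, cmp$amplitude))
  }
  invisible(x)
}

#' @export
predict.multi_gaussian_fit <- function(object, newtimes, ...) {
  amp <- vapply(object$components, `[[`, numeric(1), "amplitude")
  cen <- vapply(object$components, `[[`, numeric(1), "center")
  sig <- vapply(object$components, `[[`, numeric(1), "sigma")
  gauss_model(newtimes, amp, cen, sig, object$components[[1]]$baseline)
}

## Running-mean smoothing for peak-shape heuristics (never for fitting).
smooth_intensity <- function(y, k = 5L) {
  if (length(y) < k) return(y)
  sm <- stats::filter(y, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- y[is.na(sm)]
  as.numeric(sm)
}

## Valley-based automatic split point: the time of minimum (smoothed)
## intensity between the two most prominent peaks.
auto_split_time <- function(trace) {
  y <- smooth_intensity(trace$intensities)
  apex <- find_peak_candidates(trace$times, y, k = 2L, min_sep = 5L)
  lo <- min(apex); hi <- max(apex)
  valley <- lo + which.min(y[lo:hi]) - 1L
  trace$times[valley]
}

#' Reconstruct a wrap-around-split ATD
#'
#' In cyclic IMS a peak can split when part of the ion population completes
#' one extra lap before ejection: the faster fraction appears one cycle
#' early in the ATD. Reconstruction shifts every point earlier than
#' `split_time` forward by one cycle `period` and re-sorts by time.
#' Intensities are untouched; point count and total intensity are conserved
#' exactly.
#'
#' @param trace An [atd_trace] exhibiting peak splitting.
#' @param period Cycle period in ms (> 0), i.e. the time of one extra pass.
#' @param split_time Time (ms) separating the wrapped (earlier) segment
#'   from the rest; must lie inside the trace span. `NULL` picks the
#'   deepest valley between the two most prominent peaks automatically.
#' @return A new [atd_trace] with the wrapped segment shifted by `+period`.
#' @export
#' @seealso [inject_wraparound] for the exact inverse used in simulation.
reconstruct_wraparound <- function(trace, period, split_time = NULL) {
  stopifnot(inherits(trace, "atd_trace"))
  if (!is.finite(period) || period <= 0) {
    stop("period must be > 0", call. = FALSE)
  }
  if (is.null(split_time)) split_time <- auto_split_time(trace)
  if (split_time > max(trace$times)) {
    stop("split_time ", split_time, " ms lies beyond the trace span",
         call. = FALSE)
  }
  # split_time at or below the first point shifts nothing: identity
  shifted <- ifelse(trace$times < split_time, trace$times + period,
                    trace$times)
  o <- order(shifted)
  if (any(diff(shifted[o]) <= 0)) {
    stop("wrap-around reconstruction produced duplicate time stamps; ",
         "check the period", call. = FALSE)
  }
  atd_trace(trace$analyte_id, trace$separation_time,
            shifted[o], trace$intensities[o],
            mz = trace$mz, charge = trace$charge)
}
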