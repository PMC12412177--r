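## Synthetic cyclic-IMS arrival-time data with known ground truth.
##
## The generator renders Gaussian ATDs whose centers follow the multipass
## arrival-time model the analysis assumes:
##   t_n = bypass + n * t_pp + U(-delta, delta)
## with a uniform per-acquisition perturbation emulating the arrival-time
## fluctuations introduced by electric-field switching, additive Gaussian
## detector noise (floored at zero counts), and optional wrap-around
## splitting. Every stage of the pipeline can thus be checked against an
## exact truth table without instrument data.

#' Synthetic instrument model
#'
#' Parameter bundle describing the simulated acquisition.
#'
#' @param bypass_offset Bypass (zero-pass) arrival time, ms.
#' @param perturbation_amplitude Half-width delta of the uniform
#'   per-acquisition arrival-time perturbation, ms.
#' @param peak_sigma Gaussian ATD peak width (sigma), ms.
#' @param peak_amplitude Peak height, counts.
#' @param noise_sd Additive Gaussian intensity noise sd, counts
#'   (default 2% of the peak amplitude).
#' @param sampling_step ATD sampling interval, ms; must be smaller than
#'   `peak_sigma`.
#' @param window_halfwidth Rendered half-window around the peak center, ms.
#' @param poisson_noise Use Poisson counting noise instead of additive
#'   Gaussian noise.
#' @param wraparound_period Cycle period for wrap-around injection, ms
#'   (`NA` = none).
#' @return An `instrument_model` list.
#' @export
instrument_model <- function(bypass_offset = 5,
                             perturbation_amplitude = 0.2,
                             peak_sigma = 0.5,
                             peak_amplitude = 1000,
                             noise_sd = 0.02 * peak_amplitude,
                             sampling_step = 0.05,
                             window_halfwidth = 4,
                             poisson_noise = FALSE,
                             wraparound_period = NA_real_) {
  stopifnot(bypass_offset > 0, perturbation_amplitude >= 0,
            peak_sigma > 0, peak_amplitude > 0, noise_sd >= 0,
            sampling_step > 0, sampling_step < peak_sigma,
            window_halfwidth > 3 * peak_sigma)
  structure(list(bypass_offset = bypass_offset,
                 perturbation_amplitude = perturbation_amplitude,
                 peak_sigma = peak_sigma, peak_amplitude = peak_amplitude,
                 noise_sd = noise_sd, sampling_step = sampling_step,
                 window_halfwidth = window_halfwidth,
                 poisson_noise = poisson_noise,
                 wraparound_period = wraparound_period),
            class = "instrument_model")
}

## Default synthetic calibrant set: six singly charged lipid-like ions
## spanning the CCS range typical of protonated phospholipids.
default_synthetic_calibrants <- function() {
  data.frame(
    name = c("cal_A", "cal_B", "cal_C", "cal_D", "cal_E", "cal_F"),
    mz = c(455.5, 523.5, 600.5, 677.6, 734.6, 810.6),
    charge = rep(1L, 6),
    ccs_ref = c(205, 225, 245, 262, 278, 295),
    stringsAsFactors = FALSE)
}

render_trace <- function(analyte, t_s, center, instr, mz, charge) {
  tt <- seq(center - instr$window_halfwidth,
            center + instr$window_halfwidth,
            by = instr$sampling_step)
  y <- instr$peak_amplitude * exp(-(tt - center)^2 / (2 * instr$peak_sigma^2))
  if (instr$poisson_noise) {
    y <- stats::rpois(length(y), y)
  } else if (instr$noise_sd > 0) {
    y <- pmax(y + stats::rnorm(length(y), 0, instr$noise_sd), 0)
  }
  atd_trace(analyte, t_s, tt, y, mz = mz, charge = charge)
}

#' Generate a synthetic calibration dataset with ground truth
#'
#' For each calibrant the true perturbation-corrected periodic drift time
#' is derived from the truth power law: `t_pp = (omega'/A)^(1/B)` with
#' `omega'` the reduced-mass/charge-scaled reference CCS. Arrival times
#' follow `t_n = bypass + n * t_pp + U(-delta, delta)` and are rendered as
#' noisy Gaussian ATDs.
#'
#' Separation times: by default each calibrant gets a bypass run
#' (t_s = 0.01 ms), one single-pass run (t_s = 1.3 t_pp) and six multipass
#' runs at n = 4..9 passes (t_s = (n + 0.3) t_pp), mirroring the practice
#' of selecting separation times so every calibrant completes at least
#' four passes with six points feeding its linear model. Supplying
#' `separation_times` (which must include the 0.01 ms bypass setting and a
#' single-pass setting) instead uses the same times for all calibrants,
#' with `n = floor(t_s / t_pp)` and the perturbation drawn once per run,
#' shared across analytes.
#'
#' @param calibrants Calibrant table (`name`, `mz`, `charge`, `ccs_ref`);
#'   default: six synthetic lipid-like ions.
#' @param curve_truth Named vector `c(A = ..., B = ...)` of the truth
#'   power law.
#' @param instrument An [instrument_model].
#' @param separation_times Optional shared separation times, ms.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return List with `traces` (named list of [atd_trace]), `truth_runs`
#'   (per-acquisition truth: analyte, t_s, n, true_t_n, perturbation,
#'   role), `truth_analytes` (per-calibrant truth incl. `true_t_pp`),
#'   `calibrants`, `curve_truth`, `instrument`.
#' @export
generate_dataset <- function(calibrants = default_synthetic_calibrants(),
                             curve_truth = c(A = 200, B = 0.55),
                             instrument = instrument_model(),
                             separation_times = NULL,
                             seed = 1L) {
  stopifnot(inherits(instrument, "instrument_model"),
            all(c("A", "B") %in% names(curve_truth)))
  cal <- as.data.frame(calibrants)
  A <- curve_truth[["A"]]; B <- curve_truth[["B"]]
  mu <- reduced_mass(cal$mz * cal$charge)
  scaled <- scale_ccs(cal$ccs_ref, cal$charge, mu)
  t_pp <- (scaled / A)^(1 / B)
  shared_times <- !is.null(separation_times)
  if (shared_times && !any(separation_times <= 0.05)) {
    stop("separation_times must include the bypass setting (0.01 ms)",
         call. = FALSE)
  }
  set.seed(seed)
  delta <- instrument$perturbation_amplitude
  shared_pert <- if (shared_times && delta > 0) {
    stats::runif(length(separation_times), -delta, delta)
  }
  traces <- list(); runs <- list()
  for (i in seq_len(nrow(cal))) {
    if (shared_times) {
      ts_i <- sort(separation_times)
      n_i <- as.integer(ifelse(ts_i <= 0.05, 0, pmax(floor(ts_i / t_pp[i]), 0)))
      pert <- if (delta > 0) shared_pert[order(separation_times)]
              else rep(0, length(ts_i))
      role <- ifelse(n_i == 0L & ts_i <= 0.05, "bypass",
                     ifelse(n_i == 1L, "single-pass", "multipass"))
    } else {
      n_i <- c(0L, 1L, 4:9)
      ts_i <- c(0.01, 1.3 * t_pp[i], (4:9 + 0.3) * t_pp[i])
      pert <- if (delta > 0) stats::runif(length(ts_i), -delta, delta)
              else rep(0, length(ts_i))
      role <- c("bypass", "single-pass", rep("multipass", 6))
    }
    true_tn <- instrument$bypass_offset + n_i * t_pp[i] + pert
    for (j in seq_along(ts_i)) {
      tr <- render_trace(cal$name[i], ts_i[j], true_tn[j], instrument,
                         cal$mz[i], cal$charge[i])
      traces[[sprintf("%s__ts%g", cal$name[i], ts_i[j])]] <- tr
    }
    runs[[i]] <- data.frame(
      analyte = cal$name[i], t_s = ts_i, n = n_i, true_t_n = true_tn,
      perturbation = pert, role = role,
      flag = ifelse(n_i == 0L & role != "bypass", "no_complete_pass", ""),
      stringsAsFactors = FALSE)
  }
  truth_analytes <- data.frame(
    name = cal$name, mz = cal$mz, charge = cal$charge,
    true_ccs = cal$ccs_ref, reduced_mass = mu, scaled_ccs = scaled,
    true_t_pp = t_pp, bypass = instrument$bypass_offset,
    stringsAsFactors = FALSE)
  list(traces = traces, truth_runs = do.call(rbind, runs),
       truth_analytes = truth_analytes, calibrants = cal,
       curve_truth = c(A = A, B = B), instrument = instrument)
}

#' Inject a wrap-around split into a trace
#'
#' Moves the late `fraction` of a trace's points one cycle earlier
#' (by `-period`), producing the split ATD characteristic of part of the
#' ion population completing an extra lap. Exact inverse of
#' [reconstruct_wraparound] at the same period; the suggested split time
#' is stored as attribute `split_time` on the result.
#'
#' @param trace An [atd_trace].
#' @param period Cycle period, ms (> 0).
#' @param fraction Fraction of points (from the late end) to wrap,
#'   strictly between 0 and 1.
#' @return A split [atd_trace] with attributes `split_time` and `period`.
#' @export
inject_wraparound <- function(trace, period, fraction) {
  stopifnot(inherits(trace, "atd_trace"), period > 0,
            fraction > 0, fraction < 1)
  n <- length(trace$times)
  m <- min(max(round(fraction * n), 1L), n - 1L)
  shifted <- trace$times
  tail_idx <- (n - m + 1L):n
  shifted[tail_idx] <- shifted[tail_idx] - period
  o <- order(shifted)
  out <- atd_trace(trace$analyte_id, trace$separation_time,
                   shifted[o], trace$intensities[o],
                   mz = trace$mz, charge = trace$charge)
  # any time in (max wrapped, min unwrapped] restores the original trace
  attr(out, "split_time") <- (max(shifted[tail_idx]) + trace$times[1L]) / 2
  attr(out, "period") <- period
  out
}
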