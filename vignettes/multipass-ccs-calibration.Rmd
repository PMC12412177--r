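---
title: "Perturbation-corrected multipass CCS calibration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation-corrected multipass CCS calibration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimscal)
```

## The measurement model

Cyclic ion mobility spectrometry separates ions on a closed traveling-wave
loop; an ion that completes $n$ passes accumulates $n$ times the per-pass
drift. The measured arrival time, however, carries a systematic offset:
switching the ejection field perturbs ion velocities, so

$$ t_n = t_\mathrm{bypass} + n\, t_{pp} + \varepsilon, $$

where $t_\mathrm{bypass}$ is the transit time with the separation
effectively bypassed (recorded at $t_s = 0.01$ ms), $t_{pp}$ is the
*perturbation-corrected periodic drift time* (ms per pass), and
$\varepsilon$ collects the ejection perturbation and measurement noise.
Because $\varepsilon$ does not scale with $n$, ordinary least squares of
the total drift time $t_{nd} = t_n - t_\mathrm{bypass}$ on $n$ across
several separation times isolates $t_{pp}$ as the slope; the perturbation
lands in the intercept. This is the quantity the multipass calibration is
built on. `fit_perturbation_model()` is a plain simple regression
(`stats::lm`), exposed as a classed model object with the usual
`coef`/`predict`/`plot`/`residuals` methods, and requires at least six
included points with at least two distinct pass counts.

### Arrival-time extraction

$t_n$ is the center of a Gaussian
$a\,e^{-(t-c)^2/2\sigma^2} + b$ fitted to the ATD by Levenberg–Marquardt
(`minpack.lm::nls.lm`) under box constraints ($c$ inside the time span,
$\sigma$ positive and bounded by the span). Initialization uses moment
heuristics: center at the intensity maximum, amplitude $=\max-\min$,
baseline $=\min$, $\sigma = \mathrm{FWHM}/2.3548$ with the FWHM obtained
by linear interpolation at half height. A constant baseline is fitted by
default because raw ATDs sit on a noise floor; `baseline = FALSE`
restores a pure Gaussian for already-subtracted data. Convergence uses a
relative cost tolerance of $10^{-10}$ and a 500-iteration cap; hitting
the cap flags `converged = FALSE` rather than erroring, so batch runs can
report partial results. Fits are windowed around the most intense peak
(`pick_primary_peak()`: width six FWHM by default, earliest-time maximum
on ties), matching the convention of calibrating on the dominant
conformer. Multi-peak ATDs (e.g. isomer mixtures) are handled by a
$k$-component Gaussian sum with one shared baseline; $k$ is user-chosen,
components are initialized at the $k$ highest local maxima of a lightly
smoothed profile (5-point running mean, separation $\ge 3$ grid steps,
earlier time wins ties) and reported in descending amplitude order. The
smoothing enters initialization only; the least squares always runs on
the raw intensities.

### Pass counting and data-quality rules

The automated pass counter uses the bypass and single-pass references:
$n = \mathrm{round}\left((t_n - t_\mathrm{bypass}) / (t_{p1} -
t_\mathrm{bypass})\right)$. Ratios within 0.25 of a half-integer are
flagged ambiguous, and non-monotone pass counts across increasing
separation times trigger a warning, since both indicate unreliable
references. Two advisory thresholds mirror accepted practice: at least
**six** points per calibrant linear model (hard error), and at least
**four** passes per calibrant (warning with a per-point flag — analytes
of interest often cannot reach four passes, so this is not a hard
filter). ATDs split by wrap-around (part of the population completing an
extra lap) are detected by a two-prominent-maxima/deep-valley heuristic
and excluded with reason `"wraparound"` unless reconstructed first:
`reconstruct_wraparound()` shifts the wrapped segment forward by one
cycle period, conserving point count and total intensity exactly. When no
split time is given, the deepest valley between the two most prominent
peaks is used; this is a pragmatic rule, adequate for clearly split
peaks, and a user-supplied split time always takes precedence.

### Calibration and prediction

TW calibration removes the known mass and charge dependence before
fitting: with reduced mass $\mu = m\,m_\mathrm{gas}/(m + m_\mathrm{gas})$
(ion mass taken as $m/z \times z$, electron mass neglected; nitrogen,
28.0134 Da, by default),

$$ \Omega' = \Omega\,\sqrt{\mu}/z = A\,t^{B}, $$

fitted as simple regression in log–log space across calibrants. The
ordinate is the *scaled* CCS $\Omega'$ — the standard TW convention — and
the abscissa is $t_{pp}$ in multipass mode or $t_{p1}$ in single-pass
mode; the two curves are independent artifacts. Prediction inverts the
scaling at the analyte's own $m/z$ and $z$. Drift values outside the
calibrant range by more than 1.5× are still computed but flagged
`extrapolated` (power laws extrapolate smoothly but without support).
Percent differences against reference CCS values use the reference as
denominator and are reported to two decimals. No dead-time correction is
applied by default: the bypass subtraction already absorbs fixed transit
offsets, and a configurable constant `dead_time` is available where an
instrument needs one.

One consequence worth knowing: single-pass mode calibrates against the
raw arrival time $t_{p1}$, which still contains the bypass transit. On
data whose truth is a power law in the per-pass drift time, this shifts
the abscissa and bends the log–log line slightly, a lack of fit of a few
tenths of a percent in round-tripped CCS — visible in the test suite's
single-pass round trip, and absent from the $t_{pp}$ route. This mirrors
why the multipass workflow is preferred.

## The synthetic-data generator

`generate_dataset()` emulates exactly the structure the analysis assumes:
per-acquisition arrival times $t_n = \mathrm{bypass} + n\,t_{pp} +
U(-\delta, \delta)$ rendered as Gaussian peaks with additive Gaussian
intensity noise floored at zero (Poisson counting noise by flag). The
uniform perturbation is the simplest zero-mean model consistent with
field-switching arrival-time fluctuations; it is a stand-in for the
physics, not a simulation of it. Defaults are chosen to resemble
realistic acquisitions: bypass 5 ms, peak $\sigma$ 0.5 ms, sampling step
0.05 ms, peak amplitude 1000 counts, noise sd 2% of amplitude,
$\delta = 0.2$ ms, truth power law $A = 200$, $B = 0.55$ over six singly
charged lipid-like calibrants (CCS 205–295 Å², m/z 455–811), giving
$t_{pp}$ in the 20–40 ms range. Separation times are chosen per calibrant
as $(n + 0.3)\,t_{pp}$ for $n = 4,\dots,9$ plus a bypass run (0.01 ms)
and a single-pass run ($1.3\,t_{pp}$) — the same practice as selecting
times so every calibrant completes at least four passes with six model
points. A shared explicit time grid is also supported, with
$n = \lfloor t_s/t_{pp} \rfloor$ and the perturbation drawn once per run
and shared across analytes.

What the generator does **not** emulate: peak tailing and non-Gaussian
shapes, mobility-dependent peak broadening with pass number, space-charge
effects, m/z-domain interferences, drift of the references between runs,
and correlated perturbations beyond the per-run draw. Passing tests on
synthetic data therefore demonstrates the correctness of the estimators
under the stated model, not robustness to every instrumental pathology.

`inject_wraparound()` is the exact inverse of
`reconstruct_wraparound()` and carries its own suggested split time, so
the split/reconstruct pair can be verified to machine precision.

## Problem sizes and numerical choices

The validation runs use sizes that keep the full suite fast while leaving
no statistical ambiguity: 20 seeded replicates of the six-calibrant
end-to-end pipeline for CCS recovery (worst case ≈ 0.15% against a 0.5%
bound) and 200 replicates of a single calibrant for the mean-$t_{pp}$
check (the OLS slope is unbiased under the zero-mean perturbation; the
standard error of the mean at these settings is ≈ 0.01%, against a 0.1%
bound). Exactness checks (noiseless Gaussian, power-law and OLS
recovery) run at $10^{-6}$–$10^{-12}$ tolerances; equality between the
`lm` fit and the closed-form normal equations is asserted at $10^{-12}$
relative to the drift-time scale, since the two algorithms differ in
floating-point rounding.

File formats: the canonical on-disk dialect is a CSV long format
(`analyte, t_s, time, intensity[, mz, charge]`), written
deterministically (full-precision decimal formatting, input order) so
identical inputs give byte-identical outputs; XLSX workbooks in a
sheet-per-trace layout (`<analyte>__ts<t_s>`) are read when `readxl` is
available. Calibration curves persist as versioned JSON
(`cimscal-curve/1`, 17 significant digits, round trip better than
$10^{-12}$ relative); unknown version tags are rejected rather than
guessed at. All drift times are milliseconds, CCS in Å², masses in Da;
decimal points only.

## Limitations

Gaussian peak shapes only; the number of components $k$ of a multi-peak
fit is user-supplied, not selected automatically; the wrap-around
auto-split rule assumes a clearly bimodal trace; bypass and single-pass
references are measured per analyte (a per-tune global reference can be
emulated by passing the same values); no gases beyond a settable gas
mass, and no first-principles CCS.
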