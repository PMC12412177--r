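test_that("noiseless Gaussian parameters are recovered essentially exactly", {
  tr <- make_gaussian_trace(center = 25, sigma = 0.5, amplitude = 1000,
                            baseline = 0, from = 20, to = 30, step = 0.05)
  fit <- fit_gaussian(tr)
  expect_true(fit$converged)
  expect_equal(fit$center, 25, tolerance = 1e-6)
  expect_equal(fit$sigma, 0.5, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1000, tolerance = 1e-6)
  expect_lt(abs(fit$baseline), 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-12)
})

test_that("noiseless recovery holds across parameter combinations", {
  cases <- expand.grid(center = c(8.2, 42.7), sigma = c(0.15, 0.8, 2.0),
                       amplitude = c(120, 5e4), baseline = c(0, 35))
  for (i in seq_len(nrow(cases))) {
    p <- cases[i, ]
    tr <- make_gaussian_trace(center = p$center, sigma = p$sigma,
                              amplitude = p$amplitude, baseline = p$baseline,
                              from = p$center - 6 * p$sigma,
                              to = p$center + 6 * p$sigma,
                              step = p$sigma / 4)
    fit <- fit_gaussian(tr)
    expect_equal(fit$center, p$center, tolerance = 1e-6 * abs(p$center))
    expect_equal(fit$sigma, p$sigma, tolerance = 1e-6 * p$sigma)
    expect_equal(fit$amplitude, p$amplitude,
                 tolerance = 1e-6 * p$amplitude)
    expect_equal(fit$baseline, p$baseline,
                 tolerance = 1e-6 * max(p$amplitude, 1))
  }
})

test_that("noisy Gaussian center agrees with a dense grid-search oracle", {
  tr <- make_gaussian_trace(center = 25, sigma = 0.5, amplitude = 1000,
                            baseline = 0, from = 20, to = 30, step = 0.05,
                            noise_sd = 20, seed = 42)
  fit <- fit_gaussian(tr)
  oracle <- oracle_gaussian_grid(tr$times, tr$intensities, res = 1e-4)
  expect_lt(abs(fit$center - oracle["center"]), 0.01)
  expect_lt(abs(fit$sigma - oracle["sigma"]), 0.01)
})

test_that("degenerate inputs are rejected", {
  flat <- atd_trace("flat", 100, seq(20, 30, 0.5), rep(100, 21))
  expect_error(fit_gaussian(flat), "flat")
  tr <- make_gaussian_trace()
  expect_error(fit_gaussian(tr, window = c(100, 110)), "excludes all points")
  expect_error(pick_primary_peak(flat), "flat")
})

test_that("translation and intensity-scaling equivariance hold", {
  tr <- make_gaussian_trace(center = 25, sigma = 0.5, amplitude = 1000,
                            baseline = 50, noise_sd = 15, seed = 7)
  fit <- fit_gaussian(tr)
  for (delta in c(-3.5, 12)) {
    shifted <- atd_trace(tr$analyte_id, tr$separation_time,
                         tr$times + delta, tr$intensities)
    fs <- fit_gaussian(shifted)
    expect_equal(fs$center, fit$center + delta, tolerance = 1e-9)
    expect_equal(fs$sigma, fit$sigma, tolerance = 1e-9)
  }
  for (cf in c(0.25, 40)) {
    scaled <- atd_trace(tr$analyte_id, tr$separation_time, tr$times,
                        tr$intensities * cf)
    fc <- fit_gaussian(scaled)
    expect_equal(fc$center, fit$center, tolerance = 1e-9)
    expect_equal(fc$sigma, fit$sigma, tolerance = 1e-9)
    expect_equal(fc$amplitude, fit$amplitude * cf,
                 tolerance = 1e-9 * fit$amplitude * cf)
    expect_equal(fc$baseline, fit$baseline * cf, tolerance = 1e-6)
  }
})

test_that("primary-peak window targets the most intense feature", {
  tr <- make_two_gaussian_trace(centers = c(25, 28), sigmas = c(0.4, 0.4),
                                amplitudes = c(1000, 400),
                                from = 22, to = 31)
  w <- pick_primary_peak(tr)
  expect_true(w[1] <= 25 && 25 <= w[2])
  expect_false(w[1] <= 28 && 28 <= w[2])

  single <- make_gaussian_trace(center = 25)
  ws <- pick_primary_peak(single)
  expect_true(ws[1] <= 25 && 25 <= ws[2])

  # tie in maxima: earliest-time maximum wins
  tt <- seq(20, 30, 0.5)
  y <- rep(10, length(tt)); y[c(5, 15)] <- 100
  tie <- atd_trace("tie", 50, tt, y)
  wt <- pick_primary_peak(tie)
  expect_true(wt[1] <= tt[5] && tt[5] <= wt[2])
  expect_equal(mean(c(wt[1], wt[2])) < mean(range(tt)), TRUE)
})

test_that("multi-Gaussian fit resolves two noiseless components exactly", {
  tr <- make_two_gaussian_trace(centers = c(24, 25.5), sigmas = c(0.4, 0.4),
                                amplitudes = c(1000, 700))
  fit <- fit_multi_gaussian(tr, k = 2)
  cen <- sort(vapply(fit$components, `[[`, numeric(1), "center"))
  expect_equal(cen, c(24, 25.5), tolerance = 1e-4 / 25)
  # components sorted by descending amplitude
  amps <- vapply(fit$components, `[[`, numeric(1), "amplitude")
  expect_true(all(diff(amps) <= 0))
  expect_equal(amps[1], 1000, tolerance = 1e-6)
})

test_that("noisy two-component centers agree with the grid-search oracle", {
  tr <- make_two_gaussian_trace(centers = c(24, 25.5), sigmas = c(0.4, 0.4),
                                amplitudes = c(1000, 700), noise_sd = 20,
                                seed = 11)
  fit <- fit_multi_gaussian(tr, k = 2)
  cen <- sort(vapply(fit$components, `[[`, numeric(1), "center"))
  oracle <- oracle_two_gaussian_grid(tr$times, tr$intensities, res = 1e-3)
  expect_lt(max(abs(cen - oracle)), 0.02)
})

test_that("k = 1 multi-Gaussian fit matches fit_gaussian", {
  tr <- make_gaussian_trace(noise_sd = 10, seed = 3)
  f1 <- fit_gaussian(tr)
  fm <- fit_multi_gaussian(tr, k = 1)
  expect_equal(fm$components[[1]]$center, f1$center, tolerance = 1e-9)
  expect_equal(fm$components[[1]]$sigma, f1$sigma, tolerance = 1e-9)
  expect_equal(fm$components[[1]]$amplitude, f1$amplitude,
               tolerance = 1e-9)
})

test_that("wrap-around reconstruction conserves points and intensity", {
  tr <- make_gaussian_trace(center = 100, sigma = 0.5, from = 96, to = 104)
  split <- inject_wraparound(tr, period = 100, fraction = 0.6)
  expect_lt(min(split$times), 10)  # wrapped segment landed early
  rec <- reconstruct_wraparound(split, period = 100,
                                split_time = attr(split, "split_time"))
  expect_identical(length(rec$times), length(tr$times))
  expect_equal(sum(rec$intensities), sum(tr$intensities), tolerance = 0)
  expect_equal(rec$times, tr$times, tolerance = 1e-12)
  expect_equal(rec$intensities, tr$intensities, tolerance = 1e-12)
})

test_that("reconstruction below the trace span is the identity", {
  tr <- make_gaussian_trace()
  rec <- reconstruct_wraparound(tr, period = 100, split_time = min(tr$times))
  expect_equal(rec$times, tr$times)
  expect_equal(rec$intensities, tr$intensities)
})

test_that("reconstructed wrap-around trace refits as a single clean peak", {
  set.seed(5)
  tr <- make_gaussian_trace(center = 100, sigma = 0.5, from = 96, to = 104,
                            noise_sd = 10)
  split <- inject_wraparound(tr, period = 100, fraction = 0.5)
  # the split trace is bimodal; the raw fit leaves structured residuals
  raw_fit <- fit_gaussian(split)
  rec <- reconstruct_wraparound(split, period = 100)  # automatic split time
  rec_fit <- fit_gaussian(rec)
  expect_true(rec_fit$converged)
  expect_gt(rec_fit$r_squared, raw_fit$r_squared)
  ref_fit <- fit_gaussian(tr)
  expect_equal(rec_fit$center, ref_fit$center, tolerance = 1e-6)
})
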