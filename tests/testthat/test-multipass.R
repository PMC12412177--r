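test_that("bypass time is the fitted primary-peak center", {
  tr <- make_gaussian_trace("cal", ts = 0.01, center = 5.2, from = 3,
                            to = 8, step = 0.02)
  expect_equal(measure_bypass(tr), 5.2, tolerance = 1e-3)

  noisy <- make_gaussian_trace("cal", ts = 0.01, center = 5.2, from = 3,
                               to = 8, step = 0.02, noise_sd = 20,
                               seed = 21)
  oracle <- oracle_gaussian_grid(noisy$times, noisy$intensities,
                                 res = 1e-4)
  expect_lt(abs(measure_bypass(noisy) - oracle["center"]), 0.01)

  late <- make_gaussian_trace("cal", ts = 100, center = 25)
  expect_error(measure_bypass(late, strict = TRUE), "not a bypass")
  expect_error(measure_bypass(late, strict = FALSE), "not a bypass")
  lenient <- make_gaussian_trace("cal", ts = 0.02, center = 5.2,
                                 from = 3, to = 8)
  expect_equal(measure_bypass(lenient, strict = FALSE), 5.2,
               tolerance = 1e-3)
})

test_that("pass counting follows the single-pass/bypass ratio rule", {
  expect_identical(as.integer(count_passes(105, t_p1 = 25, bypass = 5)), 5L)
  expect_identical(as.integer(count_passes(25, t_p1 = 25, bypass = 5)), 1L)
  expect_identical(as.integer(count_passes(104.3, t_p1 = 25, bypass = 5)),
                   5L)  # ratio 4.965 rounds to 5
  expect_error(count_passes(30, t_p1 = 5, bypass = 5), "invalid reference")
  expect_error(count_passes(30, t_p1 = 4, bypass = 5), "invalid reference")
  expect_warning(count_passes(95, t_p1 = 25, bypass = 5), "ambiguous")
  # nondecreasing in t_n for fixed references
  tn <- sort(runif(50, 5, 300))
  n <- suppressWarnings(count_passes(tn, t_p1 = 25, bypass = 5))
  expect_true(all(diff(as.integer(n)) >= 0))
})

test_that("separation series carries fits, pass counts, and drift times", {
  bypass <- 5; t_pp <- 20
  ts_list <- c(40, 60, 80, 100, 120, 140)
  n_true <- floor(ts_list / t_pp)
  traces <- lapply(seq_along(ts_list), function(i) {
    make_gaussian_trace("polyala", ts = ts_list[i],
                        center = bypass + n_true[i] * t_pp,
                        from = bypass + n_true[i] * t_pp - 4,
                        to = bypass + n_true[i] * t_pp + 4)
  })
  ser <- build_separation_series(traces, bypass = bypass, t_p1 = 25)
  expect_identical(nrow(ser), 6L)
  expect_false(any(ser$excluded))
  expect_identical(ser$n_passes, as.integer(sort(n_true)))
  expect_true(all(diff(ser$n_passes) > 0))
  expect_equal(ser$total_drift, ser$n_passes * t_pp, tolerance = 1e-5)
})

test_that("wrap-around-split traces are excluded with a reason", {
  good <- make_gaussian_trace("x", ts = 100, center = 105, from = 101,
                              to = 109)
  split <- inject_wraparound(
    make_gaussian_trace("x", ts = 120, center = 125, from = 121, to = 129),
    period = 100, fraction = 0.5)
  ser <- build_separation_series(list(good, split), bypass = 5, t_p1 = 25)
  expect_identical(ser$excluded, c(TRUE, FALSE)[order(c(120, 100))])
  expect_identical(ser$reason[ser$excluded], "wraparound")
  expect_true(is.na(ser$total_drift[ser$excluded]))
})

test_that("few passes raise the advisory warning but keep the points", {
  traces <- lapply(1:3, function(n) {
    make_gaussian_trace("weak", ts = n * 20 + 5, center = 5 + n * 20,
                        from = n * 20, to = n * 20 + 10)
  })
  expect_warning(
    ser <- build_separation_series(traces, bypass = 5, t_p1 = 25),
    "minimum of 4 passes")
  expect_false(any(ser$excluded))
  expect_true(all(grepl("below_min_passes", ser$flag)))
})

test_that("perturbation model matches hand-evaluated least squares", {
  # perfect line: slope 20, intercept 0, r^2 = 1
  pts <- data.frame(n_passes = 4:9, total_drift = c(4:9) * 20)
  m <- fit_perturbation_model(pts)
  expect_equal(m$t_pp, 20, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)

  # values frozen from the closed-form normal equations
  pts2 <- data.frame(n_passes = 4:9,
                     total_drift = c(80.4, 100.6, 120.2, 140.4, 160.3,
                                     180.5))
  m2 <- fit_perturbation_model(pts2)
  expect_equal(m2$t_pp, 19.994285714285714, tolerance = 1e-12)
  expect_equal(m2$intercept, 0.437142857142858, tolerance = 1e-9)
  expect_identical(m2$n_points, 6L)
  expect_equal(unname(coef(m2)), c(m2$intercept, m2$t_pp))
})

test_that("the six-point minimum and rank checks are enforced", {
  pts <- data.frame(n_passes = 4:8, total_drift = c(4:8) * 20)
  expect_error(fit_perturbation_model(pts), "at least 6 data points")
  # excluded points do not count toward the minimum
  pts7 <- data.frame(n_passes = 4:10, total_drift = c(4:10) * 20,
                     excluded = c(rep(FALSE, 5), TRUE, TRUE))
  expect_error(fit_perturbation_model(pts7), "at least 6 data points")
  same_n <- data.frame(n_passes = rep(5L, 6), total_drift = rnorm(6, 100))
  expect_error(fit_perturbation_model(same_n), "rank-deficient")
})

test_that("adding a constant to drift times moves only the intercept", {
  set.seed(8)
  for (i in 1:20) {
    npts <- sample(6:12, 1)
    n <- sort(sample(1:15, npts, replace = TRUE))
    if (length(unique(n)) < 2) n[1] <- n[1] + 1L
    y <- 3 + 19.5 * n + rnorm(npts, 0, 0.3)
    m0 <- fit_perturbation_model(data.frame(n_passes = n, total_drift = y))
    mc <- fit_perturbation_model(
      data.frame(n_passes = n, total_drift = y + 7.25))
    expect_equal(mc$t_pp, m0$t_pp, tolerance = 1e-12)
    expect_equal(mc$intercept, m0$intercept + 7.25, tolerance = 1e-10)
  }
})

test_that("lm-based slope equals the closed-form normal equations", {
  set.seed(9)
  for (i in 1:50) {
    npts <- sample(6:12, 1)
    n <- sample(1:20, npts, replace = TRUE)
    if (length(unique(n)) < 2) n[1] <- n[1] + 1L
    y <- runif(1, 0, 5) + runif(1, 10, 30) * n + rnorm(npts, 0, 0.5)
    m <- fit_perturbation_model(data.frame(n_passes = n, total_drift = y))
    o <- ols_oracle(n, y)
    scale <- max(1, abs(y))  # 1e-12 relative to the drift-time scale
    expect_lt(abs(m$t_pp - o["slope"]), 1e-12 * scale)
    expect_lt(abs(m$intercept - o["intercept"]), 1e-12 * scale)
  }
})

test_that("slope recovery is unbiased under uniform perturbations", {
  # per-acquisition perturbation U(-delta, delta) on a known line
  set.seed(10)
  delta <- 0.2; t_pp <- 20
  slopes <- replicate(200, {
    n <- 4:9
    y <- n * t_pp + runif(6, -delta, delta)
    fit_perturbation_model(data.frame(n_passes = n, total_drift = y))$t_pp
  })
  expect_lt(abs(mean(slopes) - t_pp) / t_pp, 0.001)
  # spread consistent with the OLS standard error delta/sqrt(3 * Sxx)
  expect_lt(sd(slopes), 2 * delta / sqrt(3 * 17.5))
})
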