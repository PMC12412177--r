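# Fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_gaussian_trace <- function(analyte = "pep", ts = 100, center = 25,
                                sigma = 0.5, amplitude = 1000, baseline = 0,
                                from = center - 5, to = center + 5,
                                step = 0.05, noise_sd = 0, seed = NULL,
                                mz = NA_real_, charge = NA_integer_) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(from, to, by = step)
  y <- amplitude * exp(-(tt - center)^2 / (2 * sigma^2)) + baseline
  if (noise_sd > 0) y <- pmax(y + rnorm(length(tt), 0, noise_sd), 0)
  atd_trace(analyte, ts, tt, y, mz = mz, charge = charge)
}

make_two_gaussian_trace <- function(analyte = "iso", ts = 100,
                                    centers = c(24, 25.5),
                                    sigmas = c(0.4, 0.4),
                                    amplitudes = c(1000, 700),
                                    baseline = 0, from = 21, to = 29,
                                    step = 0.05, noise_sd = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(from, to, by = step)
  y <- rep(baseline, length(tt))
  for (j in seq_along(centers)) {
    y <- y + amplitudes[j] * exp(-(tt - centers[j])^2 / (2 * sigmas[j]^2))
  }
  if (noise_sd > 0) y <- pmax(y + rnorm(length(tt), 0, noise_sd), 0)
  atd_trace(analyte, ts, tt, y)
}

# Profiled sum of squares for a single Gaussian at fixed (center, sigma):
# amplitude and baseline enter linearly and are solved by 2x2 normal
# equations. Used by the grid-search oracle; shares no code with the
# package's Levenberg-Marquardt path.
profile_sse_1g <- function(times, y, center, sigma) {
  g <- exp(-(times - center)^2 / (2 * sigma^2))
  n <- length(y)
  sg <- sum(g); sgg <- sum(g * g); sy <- sum(y); sgy <- sum(g * y)
  det <- n * sgg - sg^2
  if (det <= 0) return(Inf)
  amp <- (n * sgy - sg * sy) / det
  base <- (sy - amp * sg) / n
  sum((y - amp * g - base)^2)
}

# Dense grid search over (center, sigma), refined in stages down to
# `res` ms resolution on each axis.
oracle_gaussian_grid <- function(times, y, res = 1e-4) {
  cc <- mean(range(times)); cw <- diff(range(times))
  sc <- diff(range(times)) / 4; sw <- diff(range(times)) / 2
  step <- min(diff(times))
  repeat {
    cg <- seq(cc - cw / 2, cc + cw / 2, length.out = 41)
    sg <- seq(max(sc - sw / 2, step / 10), sc + sw / 2, length.out = 41)
    sse <- outer(cg, sg, Vectorize(function(a, b)
      profile_sse_1g(times, y, a, b)))
    best <- arrayInd(which.min(sse), dim(sse))
    cc <- cg[best[1]]; sc <- sg[best[2]]
    dc <- cg[2] - cg[1]; ds <- sg[2] - sg[1]
    if (dc < res && ds < res) break
    cw <- 4 * dc; sw <- 4 * ds
  }
  c(center = cc, sigma = sc)
}

# Two-component oracle: grid over both centers and a shared sigma;
# amplitudes and baseline profiled by linear least squares.
oracle_two_gaussian_grid <- function(times, y, res = 1e-3) {
  span <- range(times)
  c1 <- span[1] + diff(span) / 3; c2 <- span[1] + 2 * diff(span) / 3
  cw <- diff(span) / 2
  sc <- diff(span) / 8; sw <- diff(span) / 4
  sse_at <- function(a, b, s) {
    X <- cbind(1, exp(-(times - a)^2 / (2 * s^2)),
               exp(-(times - b)^2 / (2 * s^2)))
    fit <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit)) return(Inf)
    sum((y - X %*% fit)^2)
  }
  repeat {
    g1 <- seq(c1 - cw / 2, c1 + cw / 2, length.out = 15)
    g2 <- seq(c2 - cw / 2, c2 + cw / 2, length.out = 15)
    gs <- seq(max(sc - sw / 2, 1e-3), sc + sw / 2, length.out = 9)
    best <- c(Inf, c1, c2, sc)
    for (a in g1) for (b in g2) for (s in gs) {
      v <- sse_at(a, b, s)
      if (v < best[1]) best <- c(v, a, b, s)
    }
    c1 <- best[2]; c2 <- best[3]; sc <- best[4]
    dc <- g1[2] - g1[1]
    if (dc < res) break
    cw <- 4 * dc; sw <- 4 * (gs[2] - gs[1])
  }
  sort(c(c1, c2))
}

# Closed-form simple-regression oracle: normal equations in centered
# form, slope = S_xy / S_xx with S about the means.
ols_oracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}
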