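test_that("noiseless tone: the posterior is maximised at the generating frequency only", {
  ts <- simulate_timeseries(sim_spec(omega = 0.5, n_points = 200, dt = 1))
  grid <- seq(0.001, 1, by = 0.001)
  lp <- vapply(grid, function(w) log_posterior(ts, model_spec(1), w), 0)
  expect_equal(grid[which.max(lp)], 0.5, tolerance = 1e-9)
  # no other grid point comes close to the perfect-fit peak
  expect_lt(max(lp[abs(grid - 0.5) > 1e-6]), max(lp) - 100)
})

test_that("the marginal posterior matches brute-force quadrature of the likelihood", {
  set.seed(42)
  t <- 0:7
  d <- sin(0.6 * t) + 0.3 * cos(0.6 * t) + rnorm(8, 0, 0.5)
  ts <- bsa_ts(t, d)
  omegas <- c(0.3, 0.45, 0.6, 0.8, 1.1)
  lp <- vapply(omegas, function(w) log_posterior(ts, model_spec(1), w), 0)
  lo <- vapply(omegas, function(w) quadrature_posterior(t, d, w), 0)
  ratio <- lp - lo
  expect_lt(max(abs(ratio - mean(ratio))), 1e-3)
})

test_that("pure noise yields an essentially flat posterior", {
  grid <- seq(0.05, 1.5, length.out = 50)
  ranges <- vapply(1:50, function(seed) {
    set.seed(seed)
    ts <- bsa_ts((0:99) * 3, rnorm(100))
    lp <- vapply(grid, function(w) log_posterior(ts, model_spec(1), w), 0)
    diff(range(lp))
  }, 0)
  # extreme-value bound for ~50 effectively independent flat-spectrum bins;
  # a real tone exceeds this contrast by an order of magnitude (checked)
  expect_lt(median(ranges), 6)
  lp_tone <- vapply(grid, function(w) log_posterior(row2_ts(), model_spec(1), w), 0)
  expect_gt(diff(range(lp_tone)), 10 * median(ranges))
})

test_that("coarse scans find the generating frequency", {
  sc <- bsa_scan(row2_ts(), model_spec(1), 0.05, 1.5, 300)
  step <- sc$omega_grid[2] - sc$omega_grid[1]
  expect_lt(abs(sc$mode - 0.5), step + 1e-12)

  # constant data with a constant background column: flat posterior
  tsc <- bsa_ts(0:29, rep(2, 30))
  scc <- bsa_scan(tsc, model_spec(1, 0), 0.1, 1, 50)
  expect_lt(diff(range(scc$log_post)), 1e-6)

  # 20-point short series still pins the mode near 0.5
  f <- bsa(bsa_fixture("s2_short")$ts, omega_min = 0.1)
  expect_lt(abs(f$mode - 0.5), 0.05)
})

test_that("Nelder-Mead refinement reaches the true peak", {
  ts <- row2_ts()
  spec <- model_spec(1)
  m <- refine_peak(ts, spec, 0.499)
  # golden-section oracle on the 1-D posterior
  gold <- optimize(function(w) log_posterior(ts, spec, w),
                   c(0.48, 0.52), maximum = TRUE, tol = 1e-12)
  expect_lt(abs(m - gold$maximum), 2e-3)
  expect_lt(abs(m - 0.5), 2e-3)
  # starting at the maximum is a fixed point
  expect_lt(abs(refine_peak(ts, spec, gold$maximum) - gold$maximum), 1e-6)
})

test_that("two-frequency refinement recovers both tones", {
  ts <- bsa_fixture("s4_two")$ts  # cos(0.3 t) + cos(0.5 t), 250 points
  mode <- refine_peak(ts, model_spec(2), c(0.29, 0.51), step_hint = 0.005)
  expect_lt(max(abs(sort(mode) - c(0.3, 0.5))), 5e-3)
})

test_that("fine sampling yields a proper, sharply resolved density", {
  ts <- row2_ts()
  spec <- model_spec(1)
  mode <- refine_peak(ts, spec, bsa_scan(ts, spec)$mode)
  fs <- fine_sample(ts, spec, mode)
  g <- fs$fine_grid
  tw <- c(diff(g)[1] / 2, (g[-(1:2)] - g[1:(length(g) - 2)]) / 2,
          diff(g)[length(g) - 1] / 2)
  expect_equal(sum(tw * fs$density), 1, tolerance = 1e-6)
  expect_gt(fs$sd, 1e-5)
  expect_lt(fs$sd, 1e-3)
  expect_false(fs$multimodal)
  # symmetric unimodal density: posterior mean within a grid step of the mode
  expect_lt(abs(fs$mean - fs$mode), 2 * (fs$fine_grid[2] - fs$fine_grid[1]))
  # sigma_BSA sits two orders of magnitude below sigma_FFT on the same data
  expect_lt(fs$sd, fft_summary(periodogram(ts))$sigma_fft / 100)
})

test_that("posterior precision degrades monotonically with noise", {
  med_sd <- vapply(c(1, 10, 40), function(e) {
    median(vapply(1:10, function(s) {
      ts <- simulate_timeseries(sim_spec(omega = 0.5, amp_noise_pct = e,
                                         n_points = 100, dt = 3, seed = s))
      bsa(ts)$sigma_omega
    }, 0))
  }, 0)
  expect_true(all(diff(med_sd) > 0))
})

test_that("noise and signal-to-noise estimates track the generating noise", {
  snr_med <- vapply(c(1, 40), function(e) {
    median(vapply(1:20, function(s) {
      ts <- simulate_timeseries(sim_spec(omega = 0.5, amp_noise_pct = e,
                                         n_points = 100, dt = 3, seed = s))
      bsa(ts)$snr
    }, 0))
  }, 0)
  expect_equal(snr_med[1], 70, tolerance = 0.15)
  expect_equal(snr_med[2], 1.9, tolerance = 0.2)

  # pure noise: median snr below 0.5
  snr0 <- vapply(1:50, function(s) {
    set.seed(s)
    ts <- bsa_ts((0:99) * 3, rnorm(100))
    bsa(ts)$snr
  }, 0)
  expect_lt(median(snr0), 0.5)

  expect_error(estimate_noise_snr(bsa_ts(0:4, rnorm(5)), model_spec(1, 0), 0.5),
               class = "bsa_size_error")
})

test_that("amplitude estimates invert the orthonormalisation exactly", {
  ts <- simulate_timeseries(sim_spec(omega = 0.5, amplitudes = 2,
                                     n_points = 100, dt = 3))
  a <- estimate_amplitudes(ts, model_spec(1), 0.5)
  expect_equal(unname(a$amplitudes), c(2, 0), tolerance = 1e-9)

  # noiseless sinusoid + quadratic trend: the Legendre coefficients must
  # re-express the generating polynomial (change-of-basis oracle via lm)
  spec2 <- sim_spec(omega = 0.5, trend_coeffs = c(0.02, -0.005),
                    n_points = 100, dt = 1)
  ts2 <- simulate_timeseries(spec2)
  est <- estimate_amplitudes(ts2, model_spec(1, 2), 0.5)
  X <- make_design(model_spec(1, 2), 0.5, ts2$times)
  oracle <- stats::lm.fit(X, ts2$values)$coefficients
  expect_equal(unname(est$amplitudes), unname(oracle), tolerance = 1e-8)
  # and the fitted background reproduces the generating trend pointwise
  bg_fit <- X[, 3:5] %*% est$amplitudes[3:5]
  trend <- 0.02 * ts2$times - 0.005 * ts2$times^2
  expect_lt(max(abs(bg_fit - trend)), 1e-8)

  # noisy case: the sine amplitude is within 3 posterior sds of 1
  est3 <- estimate_amplitudes(row2_ts(), model_spec(1), 0.5)
  expect_lt(abs(est3$amplitudes[["sin_w1"]] - 1), 3 * est3$se[["sin_w1"]])
})

test_that("rescaling the data leaves the mode invariant and scales the noise", {
  ts <- row2_ts()
  f1 <- bsa(ts)
  for (k in c(0.1, 7)) {
    fk <- bsa(bsa_ts(ts$times, k * ts$values))
    expect_equal(fk$mode, f1$mode, tolerance = 1e-8)
    expect_equal(fk$noise_sigma, k * f1$noise_sigma, tolerance = 1e-8)
  }
})

test_that("non-uniform sampling is handled without loss of accuracy", {
  ts <- row2_ts()
  set.seed(9)
  keep <- sort(sample(100, 70))
  sub <- bsa_ts(ts$times[keep], ts$values[keep])
  expect_lt(abs(bsa(sub)$mode - 0.5), 0.01)
})

test_that("the mode is accurate and sigma_BSA is calibrated over replicates", {
  fits <- lapply(1:100, function(s) bsa(row2_ts(seed = s)))
  err <- vapply(fits, function(f) abs(f$mode - 0.5), 0)
  expect_lt(median(err), 3e-3)
  # 50%-credible intervals (+/- 0.674 sigma_BSA for a Gaussian posterior)
  # should cover the truth for 30-70% of replicates
  cover <- vapply(fits, function(f)
    abs(f$posterior_mean - 0.5) < 0.674 * f$sigma_omega, NA)
  expect_gt(mean(cover), 0.3)
  expect_lt(mean(cover), 0.7)
})
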