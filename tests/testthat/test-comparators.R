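test_that("the periodogram has the textbook frequencies, normalisation and Parseval sum", {
  ts <- simulate_timeseries(sim_spec(omega = 0.5, n_points = 100, dt = 3))
  pg <- periodogram(ts)
  expect_equal(pg$omega, 2 * pi * (1:50) / 300, tolerance = 1e-12)
  expect_equal(pg$omega[which.max(pg$power)], pg$omega[which.min(abs(pg$omega - 0.5))])

  # Parseval: sum(power) * 2/N recovers the mean square of mean-removed data
  set.seed(2)
  tsr <- bsa_ts(0:63, rnorm(64) + 3)
  pgr <- periodogram(tsr)
  x <- tsr$values - mean(tsr$values)
  expect_equal(sum(pgr$power) * 2 / 64, mean(x^2), tolerance = 0.05)

  expect_lt(max(periodogram(bsa_ts(0:19, rep(5, 20)))$power), 1e-20)
  tsn <- bsa_ts(cumsum(runif(30, 0.5, 1.5)), rnorm(30))
  expect_error(periodogram(tsn), class = "bsa_validation_error")
})

test_that("spectrum summaries are power-weighted moments", {
  mk <- function(omega, power) structure(
    list(omega = omega, power = power), class = "bsa_spectrum")
  s1 <- fft_summary(mk(c(0.2, 0.5, 0.9), c(0, 3, 0)))
  expect_equal(s1$omega_mean, 0.5)
  expect_equal(s1$sigma_fft, 0)
  s2 <- fft_summary(mk(c(0.3, 0.7), c(2, 2)))
  expect_equal(s2$omega_mean, 0.5)
  expect_equal(s2$sigma_fft, 0.2)
  expect_error(fft_summary(mk(c(0.3, 0.7), c(0, 0))),
               class = "bsa_validation_error")
})

test_that("moving-average detrending removes slow structure only", {
  ts <- bsa_ts(0:99, 0.3 * (0:99))
  dt <- detrend_moving_average(ts, 11)
  expect_lt(max(abs(dt$values[6:94])), 1e-10)  # interior of a ramp

  spec <- sim_spec(omega = 0.5, trend_coeffs = 0.05, n_points = 200, dt = 1,
                   seed = 4)
  tsr <- simulate_timeseries(spec)
  d <- detrend_moving_average(tsr, 51)  # window of ~4 periods
  pure <- sin(0.5 * tsr$times)
  expect_gt(cor(d$values[26:175], pure[26:175]), 0.95)

  near_mean <- detrend_moving_average(bsa_ts(0:40, rnorm(41)), 39)
  expect_true(is.finite(sum(near_mean$values)))
  expect_error(detrend_moving_average(ts, 10), class = "bsa_validation_error")
  expect_error(detrend_moving_average(ts, 101), class = "bsa_validation_error")
})

test_that("the STFT matches per-segment tapered periodograms and tracks switches", {
  ts <- simulate_timeseries(sim_spec(omega = 0.5, n_points = 64, dt = 1))
  s <- stft(ts, 64, 0)
  x <- ts$values * signal::hanning(64)
  oracle <- Mod(stats::fft(x)[2:33])^2 / 64
  expect_equal(unname(s$power[1, ]), oracle[seq_len(ncol(s$power))],
               tolerance = 1e-10)

  tone <- simulate_timeseries(sim_spec(omega = 0.5, n_points = 300, dt = 1,
                                       amp_noise_pct = 5, seed = 2))
  st <- stft(tone, 50, 40)
  peaks <- st$omega[apply(st$power, 1, which.max)]
  expect_true(all(peaks == peaks[1]))

  sw <- stft(bsa_fixture("fig3_switch")$ts, 100, 5)
  dom <- sw$omega[apply(sw$power, 1, which.max)]
  expect_lt(abs(dom[1] - 0.2), 0.05)
  expect_lt(abs(dom[length(dom)] - 0.4), 0.05)

  expect_error(stft(tone, 50, 60), class = "bsa_validation_error")
})

test_that("interspike intervals recover the generating period", {
  ts <- simulate_timeseries(sim_spec(omega = 0.5, n_points = 400, dt = 0.5))
  isi <- interspike_intervals(ts)
  expect_true(all(abs(isi$intervals - 2 * pi / 0.5) <= 0.5 + 1e-9))

  # two interleaved spike trains: bimodal interval histogram
  t <- 0:299
  spikes <- rep(0, 300)
  spikes[seq(10, 290, by = 30)] <- 1
  spikes[seq(22, 290, by = 30)] <- 1.2
  isi2 <- interspike_intervals(bsa_ts(t, spikes), min_prominence = 0.5)
  expect_setequal(unique(isi2$intervals), c(12, 18))

  expect_warning(flat <- interspike_intervals(bsa_ts(0:49, rep(1, 50))),
                 class = "bsa_isi_warning")
  expect_length(flat$intervals, 0)
})

test_that("trends defeat the raw periodogram but not the BSA mode", {
  ts <- bsa_fixture("table2_row9")$ts  # sin(0.5 t) - 0.005 t^2 + 10% noise
  fsum <- fft_summary(periodogram(ts))
  expect_lt(fsum$omega_mean, 0.25)  # weighted mean collapses toward DC
  sel <- select_background_order(ts, max_order = 4)
  fit <- bsa(ts, model_spec(1, sel$selected))
  expect_lt(abs(fit$mode - 0.5), 0.01)
})

test_that("BSA precision beats the periodogram resolution limit on clean data", {
  ts <- bsa_fixture("table2_row1")$ts
  pg <- periodogram(ts)
  spacing <- 2 * pi / (100 * 3)
  expect_equal(pg$omega[2] - pg$omega[1], spacing, tolerance = 1e-12)
  expect_lt(bsa(ts)$sigma_omega, spacing)
})
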