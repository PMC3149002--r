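test_that("Laplace evidence is deterministic and prior-sensitive in the expected way", {
  ts <- row2_ts()
  pr <- evidence_priors(ts)
  e1 <- laplace_log_evidence(ts, model_spec(1), pr)
  e2 <- laplace_log_evidence(ts, model_spec(1), pr)
  expect_identical(e1$log_evidence, e2$log_evidence)
  expect_equal(e1$err, 0)
  expect_lt(abs(e1$mode - 0.5), 0.005)
  expect_true(is.finite(e1$hessian_logdet))

  # widening the frequency prior window 10x costs ~log 10 of evidence
  # (both windows kept below the sampling Nyquist limit so no alias peaks
  # enter the wider prior)
  narrow <- evidence_priors(ts, gamma_bounds = c(0.45, 0.55))
  wide <- evidence_priors(ts, gamma_bounds = c(0.03, 1.03))
  en <- laplace_log_evidence(ts, model_spec(1), narrow)
  ew <- laplace_log_evidence(ts, model_spec(1), wide)
  expect_equal(en$log_evidence - ew$log_evidence, log(10), tolerance = 0.05)
})

test_that("Laplace and nested-sampling evidences agree on a unimodal posterior", {
  diffs <- vapply(1:3, function(s) {
    ts <- row2_ts(seed = s)
    pr <- evidence_priors(ts)
    la <- laplace_log_evidence(ts, model_spec(1), pr)
    ns <- nested_sample(ts, model_spec(1),
                        ns_config(c(0.05, 1.5), n_live = 300, seed = s),
                        priors = pr)
    la$log_evidence - ns$log_evidence
  }, 0)
  expect_lt(median(abs(diffs)), 1)
})

test_that("posterior ratios require shared priors and shared data", {
  ts <- row2_ts()
  pr <- evidence_priors(ts)
  e1 <- laplace_log_evidence(ts, model_spec(1), pr)
  expect_equal(posterior_ratio(e1, e1)$ratio, 1)

  pr2 <- evidence_priors(ts, gamma_bounds = c(0.05, 2))
  e2 <- laplace_log_evidence(ts, model_spec(1), pr2)
  expect_error(posterior_ratio(e1, e2), class = "bsa_validation_error")

  ts3 <- row2_ts(seed = 99)
  e3 <- laplace_log_evidence(ts3, model_spec(1), evidence_priors(ts3))
  expect_error(posterior_ratio(e1, e3), class = "bsa_validation_error")
})

test_that("a multimodal posterior is refused by the Laplace expansion", {
  ts <- bsa_fixture("table1_caseB")$ts  # two tones: bimodal r = 1 posterior
  expect_error(laplace_log_evidence(ts, model_spec(1), evidence_priors(ts)),
               class = "bsa_multimodal_error")
})

test_that("the background ladder absorbs exactly the generating trend order", {
  # trend-free tone: the very first ratio exceeds 1 (no background wanted)
  ts0 <- row2_ts()
  sel0 <- select_background_order(ts0, max_order = 3)
  expect_equal(sel0$selected, -1L)
  expect_gt(sel0$trace$ratio[1], 1)
  expect_true(sel0$converged)
  expect_identical(sel0$status, "local")

  # linear trend: order one wins
  ts1 <- simulate_timeseries(sim_spec(omega = 0.5, amp_noise_pct = 10,
                                      trend_coeffs = 0.01, n_points = 200,
                                      dt = 1, seed = 5))
  sel1 <- select_background_order(ts1, max_order = 4)
  expect_equal(sel1$selected, 1L)

  # quadratic trend (the strongly trended benchmark): order two, with the
  # ratio trace below 1 all the way up to the order-2/order-3 comparison
  ts2 <- bsa_fixture("s1_trend")$ts
  sel2 <- select_background_order(ts2, max_order = 6)
  expect_equal(sel2$selected, 2L)
  n <- nrow(sel2$trace)
  expect_true(all(sel2$trace$ratio[seq_len(n - 1L)] < 1))
  expect_gt(sel2$trace$ratio[n], 1)
  expect_identical(sel2$trace$models[n], "H_2z/H_3z")
})

test_that("the frequency ladder prefers the generating number of tones", {
  # single tone: r = 1 wins immediately
  fsel <- select_num_frequencies(row2_ts(), max_r = 2, n_live = 200, seed = 2)
  expect_equal(fsel$selected, 1L)
  expect_gt(fsel$trace$ratio[1], 1)
  expect_false(fsel$low_evidence)

  # two tones: r = 1 loses to r = 2, r = 2 beats r = 3
  tsb <- bsa_fixture("table1_caseB")$ts
  fselb <- select_num_frequencies(tsb, max_r = 3, n_live = 200, seed = 2)
  expect_equal(fselb$selected, 2L)
  expect_lt(fselb$trace$ratio[1], 1)
  expect_gt(fselb$trace$ratio[2], 1)

  # pure noise: terminates at r = 1 and flags the poor absolute evidence
  set.seed(77)
  tsn <- bsa_ts((0:99) * 3, rnorm(100))
  fseln <- select_num_frequencies(tsn, max_r = 2, n_live = 150, seed = 3)
  expect_equal(fseln$selected, 1L)
  expect_true(fseln$low_evidence)
})

test_that("extra frequencies are penalised on single-tone data (Occam)", {
  wins <- vapply(1:10, function(s) {
    ts <- row2_ts(seed = s)
    pr <- evidence_priors(ts)
    z1 <- laplace_log_evidence(ts, model_spec(1), pr)
    z2 <- nested_sample(ts, model_spec(2),
                        ns_config(c(0.05, 1.5), n_live = 150, seed = s),
                        priors = pr)
    z1$log_evidence > z2$log_evidence
  }, NA)
  expect_gte(mean(wins), 0.9)
})

test_that("ratio traces export in the two-column table layout", {
  ts <- row2_ts()
  sel <- select_background_order(ts, max_order = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ratio_trace(sel, f)
  tab <- read.csv(f)
  expect_identical(names(tab), c("models", "ratio"))
  expect_gte(nrow(tab), 1L)
})
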