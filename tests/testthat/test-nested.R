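test_that("configuration bounds are validated", {
  expect_error(ns_config(c(0.5, 0.1)), class = "bsa_validation_error")
  expect_error(ns_config(c(0.1, 0.5), n_live = 10), class = "bsa_validation_error")
  expect_error(ns_config(c(0.1, 0.5), termination_frac = 0.5),
               class = "bsa_validation_error")
})

test_that("the sampler reproduces an analytic Gaussian evidence", {
  # L(x) = exp(-(x - 0.5)^2 / (2 s^2)), uniform prior on [0, 2]:
  # Z = s * sqrt(2 pi) * (Phi-mass inside the box) / box width
  s <- 0.05
  loglik <- function(x) -(x - 0.5)^2 / (2 * s^2)
  true_logZ <- log(s * sqrt(2 * pi) *
                   (pnorm(2, 0.5, s) - pnorm(0, 0.5, s)) / 2)
  set.seed(1)
  run <- bsafreq:::ns_loop(loglik, matrix(c(0, 2), 1), n_live = 400,
                           termination_frac = 1e-3)
  err <- sqrt(run$H / 400)
  expect_lt(abs(run$logZ - true_logZ), 3 * err)
})

test_that("identical seeds give bit-identical results", {
  ts <- row2_ts()
  cfg <- ns_config(c(0.05, 1.5), n_live = 100, seed = 42)
  a <- nested_sample(ts, model_spec(1), cfg)
  b <- nested_sample(ts, model_spec(1), cfg)
  expect_identical(a$log_evidence, b$log_evidence)
  expect_identical(a$samples, b$samples)
  # and the caller's RNG stream is untouched
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(nested_sample(ts, model_spec(1), cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("logZ scatter shrinks like 1/sqrt(n_live)", {
  s <- 0.05
  loglik <- function(x) -(x - 0.5)^2 / (2 * s^2)
  box <- matrix(c(0, 2), 1)
  scatter <- vapply(c(100L, 400L), function(nl) {
    z <- vapply(1:10, function(seed) {
      set.seed(seed)
      bsafreq:::ns_loop(loglik, box, n_live = nl, termination_frac = 1e-3)$logZ
    }, 0)
    sd(z)
  }, 0)
  # quadrupling n_live should halve the scatter, within a factor 1.5
  expect_gt(scatter[1] / scatter[2], 2 / 1.5)
  expect_lt(scatter[1] / scatter[2], 2 * 1.5)
})

test_that("NS evidence matches direct integration on a unimodal posterior", {
  ts <- row2_ts()
  ns <- nested_sample(ts, model_spec(1),
                      ns_config(c(0.05, 1.5), n_live = 300, seed = 7))
  # trapezoid oracle: coarse grid plus a fine patch around the sharp peak
  grid <- sort(unique(c(seq(0.05, 1.5, by = 0.002),
                        seq(0.49, 0.51, by = 2e-6))))
  lp <- vapply(grid, function(w) log_posterior(ts, model_spec(1), w), 0)
  mx <- max(lp)
  logI <- mx + log(sum(exp(lp - mx) * c(0, diff(grid) / 2) +
                       exp(lp - mx) * c(diff(grid) / 2, 0)))
  log_oracle <- logI - log(1.5 - 0.05)  # uniform prior over the box
  expect_lt(abs(ns$log_evidence - log_oracle), 3 * ns$log_evidence_err)
})

test_that("a bimodal posterior is integrated and both modes are populated", {
  ts <- bsa_fixture("table1_caseB")$ts  # tones at 0.3 and 0.5, r = 1 model
  ns <- nested_sample(ts, model_spec(1),
                      ns_config(c(0.05, 1.5), n_live = 400, seed = 11))
  w <- ns$samples[, "weight"]
  om <- ns$samples[, 1]
  m1 <- sum(w[abs(om - 0.3) < 0.02])
  m2 <- sum(w[abs(om - 0.5) < 0.02])
  expect_gt(m1, 0.1)
  expect_gt(m2, 0.1)
  expect_gt(m1 + m2, 0.9)
  # grid-integration oracle over the same box
  grid <- sort(unique(c(seq(0.05, 1.5, by = 0.002),
                        seq(0.29, 0.31, by = 2e-6),
                        seq(0.49, 0.51, by = 2e-6))))
  lp <- vapply(grid, function(w) log_posterior(ts, model_spec(1), w), 0)
  mx <- max(lp)
  logI <- mx + log(sum(exp(lp - mx) * c(0, diff(grid) / 2) +
                       exp(lp - mx) * c(diff(grid) / 2, 0)))
  expect_lt(abs(ns$log_evidence - (logI - log(1.45))),
            3 * ns$log_evidence_err)
})

test_that("weights normalise and summaries respect component ordering", {
  ts <- bsa_fixture("s4_two")$ts
  ns <- nested_sample(ts, model_spec(2),
                      ns_config(c(0.1, 0.8), n_live = 150, seed = 3))
  expect_equal(sum(ns$samples[, "weight"]), 1, tolerance = 1e-8)
  expect_true(all(ns$samples[, 1] <= ns$samples[, 2]))
  expect_lt(max(abs(ns$omega_mean - c(0.3, 0.5))), 0.01)
  expect_true(all(ns$omega_sd >= 0))
  expect_gt(ns$log_evidence_err, 0)
})
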