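# Independent numerical oracles shared across test files. These never call
# the code paths they validate: orthonormalisation comes from QR, residuals
# from lm.fit, and the marginalisation integral from Simpson quadrature of
# the explicit Gaussian likelihood.

simpson_weights <- function(n, h) {
  stopifnot(n %% 2L == 1L)
  w <- rep(c(4, 2), length.out = n - 2L)
  c(1, w, 1) / 3 * h
}

# Brute-force marginal posterior at one omega: quadrature of the Gaussian
# likelihood over the amplitudes of a QR-orthonormalised sinusoid basis
# (uniform, -10..10) and the noise scale (Jeffreys, 0.01..100).
quadrature_posterior <- function(times, values, omega, n_amp = 401L,
                                 n_sig = 161L) {
  X <- cbind(sin(omega * times), cos(omega * times))
  H <- qr.Q(qr(X))
  h <- drop(crossprod(H, values))
  N <- length(values)
  a <- seq(-10, 10, length.out = n_amp)
  lsig <- seq(log(0.01), log(100), length.out = n_sig)
  wa <- simpson_weights(n_amp, a[2L] - a[1L])
  ws <- simpson_weights(n_sig, lsig[2L] - lsig[1L])
  Sdd <- sum(values^2)
  SSR <- outer(a, a, function(A, B) Sdd - 2 * A * h[1L] - 2 * B * h[2L] +
                 A^2 + B^2)
  W2 <- outer(wa, wa)
  tot <- 0
  for (i in seq_along(lsig)) {
    sg <- exp(lsig[i])
    tot <- tot + ws[i] * sum(W2 * exp(-SSR / (2 * sg^2))) *
      (2 * pi * sg^2)^(-N / 2)
  }
  log(tot)
}

# Least-squares residual sum of squares via lm.fit (residual identity oracle).
lsq_rss <- function(design, values) {
  fit <- stats::lm.fit(design, values)
  sum(fit$residuals^2)
}

# Explicit low-order Legendre polynomials (closed forms, independent of the
# recurrence used by the package).
legendre_explicit <- function(x, k) {
  switch(as.character(k),
         "0" = rep(1, length(x)),
         "1" = x,
         "2" = (3 * x^2 - 1) / 2,
         "3" = (5 * x^3 - 3 * x) / 2,
         "4" = (35 * x^4 - 30 * x^2 + 3) / 8,
         stop("order not tabulated"))
}

# Canonical noisy single-tone trace used in many tests: unit sine at
# 0.5 rad/s, 10% additive noise, 100 points at 3 s spacing.
row2_ts <- function(seed = 1) bsa_fixture("table2_row2", seed = seed)$ts
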