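#' Log marginal posterior of the angular frequencies
#'
#' The Bretthorst marginal posterior: with uniform priors on the expansion
#' amplitudes and the frequencies and a Jeffreys prior on the noise scale,
#' integrating amplitudes and noise out of the Gaussian likelihood leaves
#'
#' \deqn{\log P(\omega | D) = \frac{m - N}{2}
#'       \log\left(1 - \frac{m \bar{h}^2}{N \bar{d}^2}\right) + const,}
#'
#' computed here with `log1p` so that the exponent `(m - N)/2` does not
#' underflow for long series. `m*h2_bar/(N*d2_bar)` is the fraction of the
#' data power captured by the (orthonormalised) model at this `omega`.
#'
#' @param ts A [bsa_ts()].
#' @param spec A [model_spec()].
#' @param omega Numeric vector of angular frequencies (length `spec$n_freq`),
#'   rad per native time unit.
#' @return Unnormalised log posterior (scalar). For numerically perfect fits
#'   (captured power indistinguishable from total power) a finite cap
#'   `((N - m)/2) * log(1/eps_machine)` is returned.
#' @export
log_posterior <- function(ts, spec, omega) {
  st <- marginal_stats(ts$times, ts$values, spec, omega)
  log_posterior_from_stats(st)
}

# Fast sufficient-stats path: h = R^{-T} X'd needs only an m-vector
# triangular solve, never the full orthonormalised N x m basis. The design
# is built inline (no names, minimal validation) because this sits inside
# every scan, refinement and nested-sampling iteration.
marginal_stats <- function(times, values, spec, omega) {
  r <- spec$n_freq
  bg <- spec$background_order
  N <- length(times)
  m <- 2L * r + bg + 1L
  if (m >= N) {
    bsa_stop("bsa_size_error", sprintf(
      "model has m = %d functions but only N = %d data points", m, N))
  }
  if (any(omega <= 0) || (r > 1L && anyDuplicated(omega))) {
    bsa_stop("bsa_degenerate_basis", "invalid or duplicate frequencies")
  }
  X <- matrix(0, N, m)
  for (k in seq_len(r)) {
    wt <- omega[k] * times
    X[, 2L * k - 1L] <- sin(wt)
    X[, 2L * k] <- cos(wt)
  }
  if (bg >= 0L) {
    tau <- 2 * (times - times[1L]) / (times[N] - times[1L]) - 1
    X[, (2L * r + 1L):m] <- legendre_matrix(tau, bg)
  }
  G <- crossprod(X)
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R) || rcond(G) < 1e-12) {
    bsa_stop("bsa_degenerate_basis",
             "design matrix is (numerically) rank deficient at this omega")
  }
  h <- backsolve(R, crossprod(X, values), transpose = TRUE)
  list(N = N, m = m, h2_bar = sum(h^2) / m, d2_bar = sum(values^2) / N)
}

log_posterior_from_stats <- function(st) {
  N <- st$N
  m <- st$m
  if (st$d2_bar <= 0) return(0)  # all-zero data: flat posterior
  frac <- (m * st$h2_bar) / (N * st$d2_bar)
  eps <- .Machine$double.eps
  if (frac >= 1 - eps) {
    return(((N - m) / 2) * log(1 / eps))
  }
  ((m - N) / 2) * log1p(-frac)
}

# Vectorised safe evaluation over a frequency grid; degenerate bases give NA.
log_posterior_grid <- function(ts, spec, grid) {
  vapply(grid, function(w) {
    tryCatch(log_posterior(ts, spec, w),
             bsa_error = function(e) NA_real_)
  }, numeric(1))
}

#' Scan the marginal posterior over a frequency grid
#'
#' Evaluates the single-frequency log posterior on a uniform grid over
#' `(omega_min, omega_max]` and records the provisional mode. Scans are
#' one-dimensional; multi-frequency models are explored with
#' [nested_sample()] or refined from a starting tuple with [refine_peak()].
#'
#' @param ts A [bsa_ts()].
#' @param spec A [model_spec()] with `n_freq = 1`.
#' @param omega_min,omega_max Scan window, rad per time unit, `0 < min < max`.
#' @param n_grid Number of grid points (>= 10).
#' @return A list of class `bsa_scan` with `omega_grid`, `log_post` and
#'   `mode` (the grid argmax; ties broken toward the lower frequency).
#' @export
bsa_scan <- function(ts, spec, omega_min = 0.05, omega_max = 1.5,
                     n_grid = 300L) {
  stopifnot(inherits(ts, "bsa_ts"), inherits(spec, "bsa_model_spec"))
  if (spec$n_freq != 1L) {
    bsa_stop("bsa_validation_error",
             "bsa_scan is one-dimensional; use nested_sample for n_freq > 1")
  }
  if (!(omega_min > 0 && omega_max > omega_min)) {
    bsa_stop("bsa_validation_error", "need 0 < omega_min < omega_max")
  }
  if (n_grid < 10L) bsa_stop("bsa_validation_error", "n_grid must be >= 10")
  grid <- seq(omega_min, omega_max, length.out = n_grid)
  lp <- log_posterior_grid(ts, spec, grid)
  if (all(is.na(lp))) {
    bsa_stop("bsa_degenerate_basis", "posterior undefined at every grid point")
  }
  mode <- grid[which.max(lp)]  # which.max returns the first (lowest) maximum
  structure(list(omega_grid = grid, log_post = lp, mode = mode),
            class = "bsa_scan")
}

#' Refine a posterior peak by Nelder-Mead simplex maximisation
#'
#' @param ts A [bsa_ts()].
#' @param spec A [model_spec()].
#' @param omega_start Starting tuple (length `spec$n_freq`), typically the
#'   grid mode from [bsa_scan()].
#' @param step_hint Scale of the initial simplex: its edge is
#'   `2 * step_hint` per component (pass the coarse grid step).
#' @param abstol Absolute convergence tolerance on the log posterior.
#' @return The refined frequency tuple. Emits a warning and returns the best
#'   point found if the simplex does not converge.
#' @export
refine_peak <- function(ts, spec, omega_start, step_hint = 0.005,
                        abstol = 1e-10) {
  stopifnot(length(omega_start) == spec$n_freq)
  neg <- function(w) {
    if (any(w <= 0) || anyDuplicated(w)) return(1e300)
    lp <- tryCatch(log_posterior(ts, spec, w),
                   bsa_error = function(e) NA_real_)
    if (is.na(lp)) 1e300 else -lp
  }
  # optim's simplex edge is 0.1 * parscale, so parscale = 20 * step_hint
  # realises an initial edge of 2 grid steps
  # reltol, not optim's abstol (the latter is a reach-zero criterion that
  # fires immediately on negative objectives); at |log posterior| ~ 1e2-1e4
  # a relative 1e-15 realises the ~1e-10 absolute target
  run_nm <- function(start, scale) suppressWarnings(stats::optim(
    start, neg, method = "Nelder-Mead",
    control = list(reltol = max(1e-12, abstol * 0.01),
                   parscale = rep(scale, spec$n_freq),
                   maxit = 500L * spec$n_freq)))
  fit <- run_nm(omega_start, 20 * step_hint)
  # restart with a contracted simplex: guards against premature collapse
  fit2 <- run_nm(fit$par, 2 * step_hint)
  if (fit2$value < fit$value) fit <- fit2
  if (fit$convergence != 0L) {
    bsa_warn("bsa_convergence_warning",
             "Nelder-Mead did not converge; returning the best point found")
  }
  best <- if (fit$value <= neg(omega_start)) fit$par else omega_start
  if (spec$n_freq == 1L) {
    # golden-section polish: the simplex can stall on extremely sharp peaks
    op <- stats::optimize(function(w) neg(w), lower = best - 2 * step_hint,
                          upper = best + 2 * step_hint, tol = 1e-12)
    if (op$objective < neg(best)) best <- op$minimum
  }
  best
}

# Trapezoid weights for a (uniform or not) grid.
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1L] <- (x[2L] - x[1L]) / 2
  w[n] <- (x[n] - x[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  w
}

# Count local maxima above `frac` of the peak density (1-D).
count_modes_1d <- function(dens, frac = 0.01) {
  n <- length(dens)
  if (n < 3L) return(1L)
  thr <- frac * max(dens)
  up <- dens[2:(n - 1L)] > dens[1:(n - 2L)] & dens[2:(n - 1L)] >= dens[3:n]
  sum(up & dens[2:(n - 1L)] > thr) + as.integer(dens[1L] > dens[2L] && dens[1L] > thr) +
    as.integer(dens[n] > dens[n - 1L] && dens[n] > thr)
}

#' Finely sample the posterior around a located mode
#'
#' Normalises the posterior density over a window around the mode and
#' summarises it: posterior mean and standard deviation (`sigma_BSA`) per
#' frequency component, and a multimodality flag (count of local maxima
#' above 1% of the peak). The window widens (up to 3 times) when more than
#' 1% of the mass touches an edge, and contracts when the posterior turns
#' out to be much sharper than the initial window, so that `sigma_BSA` is
#' resolved by the grid.
#'
#' @param ts A [bsa_ts()].
#' @param spec A [model_spec()] with `n_freq` of 1 or 2.
#' @param mode Frequency tuple from [refine_peak()].
#' @param half_width Initial half-width of the sampling window (rad/time).
#' @param n_fine Number of grid points per component.
#' @return A list of class `bsa_fine` with `fine_grid`, `fine_log_post`,
#'   `density` (normalised; for two frequencies also `marginals`),
#'   `mean`, `sd`, `mode`, `n_modes` and `multimodal`.
#' @export
fine_sample <- function(ts, spec, mode, half_width = 0.05, n_fine = 201L) {
  r <- spec$n_freq
  stopifnot(length(mode) == r, r %in% c(1L, 2L))
  if (r == 1L) fine_sample_1d(ts, spec, mode, half_width, n_fine)
  else fine_sample_2d(ts, spec, mode, half_width, n_fine)
}

fine_sample_1d <- function(ts, spec, mode, half_width, n_fine) {
  widen <- 0L
  passes <- 0L
  repeat {
    passes <- passes + 1L
    lo <- max(mode - half_width, 1e-9)
    hi <- mode + half_width
    grid <- seq(lo, hi, length.out = n_fine)
    lp <- log_posterior_grid(ts, spec, grid)
    lp[is.na(lp)] <- -Inf
    dens <- exp(lp - max(lp))
    w <- trapz_weights(grid)
    Z <- sum(w * dens)
    dens <- dens / Z
    edge <- max(dens[1L], dens[n_fine]) * (grid[2L] - grid[1L])
    if (edge > 0.01 && widen < 3L) {
      half_width <- 2 * half_width
      widen <- widen + 1L
      next
    }
    if (edge > 0.01) {
      bsa_warn("bsa_truncation_warning",
               "posterior mass still truncated after widening the fine window")
    }
    mu <- sum(w * dens * grid)
    sd <- sqrt(max(0, sum(w * dens * (grid - mu)^2)))
    step <- grid[2L] - grid[1L]
    # Contract until the posterior sd is resolved by many grid steps.
    if (passes < 6L && is.finite(sd) && sd > 0 && sd < 8 * step &&
        half_width > 10 * sd) {
      half_width <- max(8 * sd, 5 * step)
      next
    }
    n_modes <- count_modes_1d(dens)
    return(structure(list(
      fine_grid = grid, fine_log_post = lp, density = dens,
      mean = mu, sd = sd, mode = grid[which.max(lp)],
      n_modes = n_modes, multimodal = n_modes > 1L), class = "bsa_fine"))
  }
}

fine_sample_2d <- function(ts, spec, mode, half_width, n_fine) {
  if (length(half_width) == 1L) half_width <- rep(half_width, 2L)
  n_fine <- min(n_fine, 81L)  # tensor grid: keep the cost quadratic-but-small
  for (pass in 1:4) {
    g1 <- seq(max(mode[1L] - half_width[1L], 1e-9), mode[1L] + half_width[1L],
              length.out = n_fine)
    g2 <- seq(max(mode[2L] - half_width[2L], 1e-9), mode[2L] + half_width[2L],
              length.out = n_fine)
    lp <- matrix(-Inf, n_fine, n_fine)
    for (i in seq_len(n_fine)) {
      for (j in seq_len(n_fine)) {
        if (abs(g1[i] - g2[j]) < 1e-12) next
        v <- tryCatch(log_posterior(ts, spec, c(g1[i], g2[j])),
                      bsa_error = function(e) NA_real_)
        if (!is.na(v)) lp[i, j] <- v
      }
    }
    dens <- exp(lp - max(lp))
    w1 <- trapz_weights(g1)
    w2 <- trapz_weights(g2)
    Z <- drop(w1 %*% dens %*% w2)
    dens <- dens / Z
    marg1 <- drop(dens %*% w2)
    marg2 <- drop(w1 %*% dens)
    mu <- c(sum(w1 * marg1 * g1), sum(w2 * marg2 * g2))
    sd <- c(sqrt(max(0, sum(w1 * marg1 * (g1 - mu[1L])^2))),
            sqrt(max(0, sum(w2 * marg2 * (g2 - mu[2L])^2))))
    step <- c(g1[2L] - g1[1L], g2[2L] - g2[1L])
    contract <- is.finite(sd) & sd > 0 & sd < 6 * step & half_width > 8 * sd
    if (any(contract) && pass < 4L) {
      half_width[contract] <- pmax(8 * sd[contract], 4 * step[contract])
      next
    }
    idx <- arrayInd(which.max(lp), dim(lp))
    n_modes <- count_modes_2d(dens)
    return(structure(list(
      fine_grid = list(g1, g2), fine_log_post = lp, density = dens,
      marginals = list(marg1, marg2),
      mean = mu, sd = sd, mode = c(g1[idx[1L]], g2[idx[2L]]),
      n_modes = n_modes, multimodal = n_modes > 1L), class = "bsa_fine"))
  }
}

count_modes_2d <- function(dens, frac = 0.01) {
  nr <- nrow(dens)
  nc <- ncol(dens)
  thr <- frac * max(dens)
  count <- 0L
  for (i in 2:(nr - 1L)) {
    for (j in 2:(nc - 1L)) {
      v <- dens[i, j]
      if (v <= thr) next
      nb <- dens[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
      if (v >= max(nb)) count <- count + 1L
    }
  }
  max(count, 1L)
}

#' Posterior noise level and signal-to-noise ratio
#'
#' The posterior-expected noise power given the model at the located mode is
#' `sigma^2 = (N*d2_bar - m*h2_bar) / (N - m - 2)`, the residual power
#' spread over the residual degrees of freedom of the marginalised model.
#' The signal-to-noise ratio divides the RMS of the *sinusoidal* part of the
#' fit by `sigma`; background columns are excluded because including them
#' inflates the ratio whenever a trend is present.
#'
#' @param ts A [bsa_ts()].
#' @param spec A [model_spec()].
#' @param mode Frequency tuple at which to evaluate.
#' @return A list with `noise_sigma` (signal units) and `snr`
#'   (dimensionless).
#' @export
estimate_noise_snr <- function(ts, spec, mode) {
  X <- make_design(spec, mode, ts$times)
  B <- orthonormalize(X)
  st <- sufficient_stats(ts$values, B)
  N <- st$N
  m <- st$m
  if (N <= m + 2L) {
    bsa_stop("bsa_size_error", sprintf(
      "need N > m + 2 for the noise estimate (N = %d, m = %d)", N, m))
  }
  resid2 <- max(0, N * st$d2_bar - m * st$h2_bar)
  noise_sigma <- sqrt(resid2 / (N - m - 2L))
  amps <- backsolve(st$chol_factor, st$h)
  sig_cols <- seq_len(2L * spec$n_freq)
  signal_fit <- X[, sig_cols, drop = FALSE] %*% amps[sig_cols]
  snr <- if (noise_sigma > 0) sqrt(mean(signal_fit^2)) / noise_sigma else Inf
  list(noise_sigma = noise_sigma, snr = snr)
}

#' Posterior-mean amplitude estimates
#'
#' Amplitudes are nuisance parameters of BSA - they are marginalised before
#' any frequency inference - but once a mode is located their posterior
#' means equal the least-squares coefficients, recovered in the original
#' (non-orthonormal) basis through the stored Cholesky factor.
#'
#' @param ts A [bsa_ts()].
#' @param spec A [model_spec()].
#' @param mode Frequency tuple.
#' @return A list with `amplitudes` (named, original basis) and `se`
#'   (posterior standard deviations, from the noise estimate and the Gram
#'   matrix).
#' @export
estimate_amplitudes <- function(ts, spec, mode) {
  X <- make_design(spec, mode, ts$times)
  B <- orthonormalize(X)
  st <- sufficient_stats(ts$values, B)
  amps <- drop(backsolve(st$chol_factor, st$h))
  names(amps) <- colnames(X)
  ns <- tryCatch(estimate_noise_snr(ts, spec, mode)$noise_sigma,
                 bsa_error = function(e) NA_real_)
  Rinv <- backsolve(st$chol_factor, diag(st$m))
  se <- ns * sqrt(rowSums(Rinv^2))
  names(se) <- colnames(X)
  list(amplitudes = amps, se = se)
}

#' Full single-frequency BSA analysis of one trace
#'
#' Convenience pipeline: coarse scan, Nelder-Mead refinement, fine sampling
#' around the peak, then noise / signal-to-noise / amplitude summaries.
#'
#' @inheritParams bsa_scan
#' @param fine_n Grid points for [fine_sample()].
#' @return An object of class `bsa_posterior` collecting the scan, the
#'   refined `mode`, `sigma_omega`, `posterior_mean`, `noise_sigma`, `snr`,
#'   `amplitudes`, the fine grid products and a `multimodal` flag.
#' @examples
#' ts <- simulate_timeseries(sim_spec(omega = 0.5, n_points = 100, dt = 3,
#'                                    amp_noise_pct = 10, seed = 1))
#' fit <- bsa(ts, model_spec(1))
#' fit$mode
#' @export
bsa <- function(ts, spec = model_spec(1L), omega_min = 0.05, omega_max = 1.5,
                n_grid = 300L, fine_n = 201L) {
  sc <- bsa_scan(ts, spec, omega_min, omega_max, n_grid)
  step <- sc$omega_grid[2L] - sc$omega_grid[1L]
  mode <- refine_peak(ts, spec, sc$mode, step_hint = step)
  fs <- fine_sample(ts, spec, mode, half_width = 5 * step, n_fine = fine_n)
  nsr <- estimate_noise_snr(ts, spec, mode)
  amp <- estimate_amplitudes(ts, spec, mode)
  structure(list(
    omega_grid = sc$omega_grid, log_post = sc$log_post,
    mode = fs$mode, sigma_omega = fs$sd, posterior_mean = fs$mean,
    noise_sigma = nsr$noise_sigma, snr = nsr$snr,
    amplitudes = amp$amplitudes, amplitude_se = amp$se,
    fine_grid = fs$fine_grid, fine_log_post = fs$fine_log_post,
    fine_density = fs$density, n_modes = fs$n_modes,
    multimodal = fs$multimodal, spec = spec, label = ts$label),
    class = "bsa_posterior")
}

#' @export
print.bsa_posterior <- function(x, ...) {
  cat(sprintf("<bsa_posterior> '%s'\n", x$label))
  cat(sprintf("  mode:   omega = %.6g rad/time  (period %.6g)\n",
              x$mode[1L], 2 * pi / x$mode[1L]))
  cat(sprintf("  sigma_BSA = %.3g rad/time\n", x$sigma_omega[1L]))
  cat(sprintf("  noise sigma = %.3g, snr = %.3g\n", x$noise_sigma, x$snr))
  if (x$multimodal) {
    cat("  NOTE: posterior is multimodal in the fine window;",
        "consider nested_sample()\n")
  }
  invisible(x)
}

#' Export a posterior curve as a two-column CSV
#'
#' @param fit A `bsa_posterior` (or `bsa_fine`) object.
#' @param path Output path; columns `omega`, `density`.
#' @return `path`, invisibly.
#' @export
write_posterior_curve <- function(fit, path) {
  grid <- if (is.list(fit$fine_grid)) fit$fine_grid[[1L]] else fit$fine_grid
  dens <- if (is.matrix(fit$fine_density)) {
    if (is.null(fit$marginals)) rowSums(fit$fine_density) else fit$marginals[[1L]]
  } else fit$fine_density
  utils::write.csv(data.frame(omega = grid, density = dens), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
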