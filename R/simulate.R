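#' Specify a synthetic oscillatory test signal
#'
#' The simulator regenerates the harmonic test fixtures used throughout the
#' package's validation: unit-amplitude tones with additive Gaussian noise,
#' optional per-sample Gaussian phase jitter, polynomial background trends,
#' harmonic stacks, piecewise frequency switches and linear chirps.
#'
#' The data model is
#' `d(t_i) = sum_k A_k sin(w_k t_i + phi_k + eta_ki) + poly(t_i) + eps_i`
#' with `eps_i ~ N(0, (amp_noise_pct/100)^2)` - the noise level is a
#' percentage of the unit tone amplitude, so 10% means sd 0.1 - and
#' `eta_ki ~ N(0, (phase_noise_pct/100 * 2*pi)^2)` drawn independently per
#' sample and tone.
#'
#' @param omega Angular frequencies of the tones (rad per time unit). For
#'   `waveform = "freq_switch"` and `"chirp"`, exactly two values: start
#'   and end frequency.
#' @param amplitudes Per-tone amplitudes (default 1).
#' @param phases Per-tone phases in radians (default 0).
#' @param amp_noise_pct Additive Gaussian noise sd, percent of unit
#'   amplitude.
#' @param phase_noise_pct Per-sample phase jitter sd, percent of `2*pi`.
#' @param trend_coeffs Polynomial trend coefficients `c(a1, a2, ...)` for
#'   `a1*t + a2*t^2 + ...` (no constant term by default; prepend via
#'   `trend_intercept`).
#' @param trend_intercept Constant offset.
#' @param n_points Number of samples N.
#' @param dt Sampling interval (ignored when `times` is given).
#' @param times Optional explicit (possibly non-uniform) sampling times.
#' @param t0 Start time when sampling uniformly.
#' @param waveform One of `"harmonic"`, `"harmonic_stack"` (adds the 3rd
#'   and 5th harmonic of `omega[1]`), `"freq_switch"` (switches from
#'   `omega[1]` to `omega[2]` at `switch_time`, default the midpoint) or
#'   `"chirp"` (instantaneous frequency linear from `omega[1]` to
#'   `omega[2]`).
#' @param switch_time Switch time for `"freq_switch"`.
#' @param seed Integer seed; identical specs yield bit-identical series.
#' @param use_cos Use cosines instead of sines for the tones.
#' @return An object of class `bsa_sim_spec`.
#' @export
sim_spec <- function(omega = 0.5, amplitudes = NULL, phases = NULL,
                     amp_noise_pct = 0, phase_noise_pct = 0,
                     trend_coeffs = numeric(0), trend_intercept = 0,
                     n_points = 100L, dt = 3, times = NULL, t0 = 0,
                     waveform = c("harmonic", "harmonic_stack",
                                  "freq_switch", "chirp"),
                     switch_time = NULL, seed = 1L, use_cos = FALSE) {
  waveform <- match.arg(waveform)
  if (any(omega <= 0)) bsa_stop("bsa_validation_error", "omega must be positive")
  if (waveform %in% c("freq_switch", "chirp") && length(omega) != 2L) {
    bsa_stop("bsa_validation_error",
             sprintf("waveform '%s' needs exactly two frequencies", waveform))
  }
  if (is.null(amplitudes)) amplitudes <- rep(1, length(omega))
  if (is.null(phases)) phases <- rep(0, length(omega))
  structure(list(omega = omega, amplitudes = amplitudes, phases = phases,
                 amp_noise_pct = amp_noise_pct,
                 phase_noise_pct = phase_noise_pct,
                 trend_coeffs = trend_coeffs,
                 trend_intercept = trend_intercept,
                 n_points = as.integer(n_points), dt = dt, times = times,
                 t0 = t0, waveform = waveform, switch_time = switch_time,
                 seed = as.integer(seed), use_cos = use_cos),
            class = "bsa_sim_spec")
}

#' Generate a time series from a simulation spec
#'
#' @param spec A [sim_spec()].
#' @param label Trace label; defaults to the waveform name.
#' @return A [bsa_ts()]; identical `spec` (including `seed`) gives a
#'   bit-identical result, with the caller's RNG stream left untouched.
#' @examples
#' ts <- simulate_timeseries(sim_spec(omega = 0.5, amp_noise_pct = 10,
#'                                    n_points = 100, dt = 3, seed = 7))
#' @export
simulate_timeseries <- function(spec, label = NULL) {
  stopifnot(inherits(spec, "bsa_sim_spec"))
  t <- if (!is.null(spec$times)) as.numeric(spec$times) else
    spec$t0 + (seq_len(spec$n_points) - 1L) * spec$dt
  N <- length(t)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  osc <- numeric(N)
  base_fun <- if (spec$use_cos) cos else sin
  jitter_sd <- spec$phase_noise_pct / 100 * 2 * pi
  tone <- function(w, A, phi) {
    eta <- if (jitter_sd > 0) stats::rnorm(N, 0, jitter_sd) else 0
    A * base_fun(w * t + phi + eta)
  }
  switch (spec$waveform,
    harmonic = {
      for (k in seq_along(spec$omega)) {
        osc <- osc + tone(spec$omega[k], spec$amplitudes[k], spec$phases[k])
      }
    },
    harmonic_stack = {
      w <- spec$omega[1L]
      for (mult in c(1, 3, 5)) {
        osc <- osc + tone(mult * w, spec$amplitudes[1L], spec$phases[1L])
      }
    },
    freq_switch = {
      tsw <- if (is.null(spec$switch_time)) (t[1L] + t[N]) / 2 else
        spec$switch_time
      eta <- if (jitter_sd > 0) stats::rnorm(N, 0, jitter_sd) else 0
      w <- ifelse(t < tsw, spec$omega[1L], spec$omega[2L])
      osc <- spec$amplitudes[1L] * base_fun(w * t + spec$phases[1L] + eta)
    },
    chirp = {
      # instantaneous frequency linear in t; phase is its time integral
      span <- t[N] - t[1L]
      u <- (t - t[1L]) / span
      phase <- spec$omega[1L] * (t - t[1L]) +
        (spec$omega[2L] - spec$omega[1L]) * span * u^2 / 2
      eta <- if (jitter_sd > 0) stats::rnorm(N, 0, jitter_sd) else 0
      osc <- spec$amplitudes[1L] * base_fun(phase + spec$phases[1L] + eta)
    }
  )

  trend <- rep(spec$trend_intercept, N)
  for (p in seq_along(spec$trend_coeffs)) {
    trend <- trend + spec$trend_coeffs[p] * t^p
  }
  eps <- if (spec$amp_noise_pct > 0) {
    stats::rnorm(N, 0, spec$amp_noise_pct / 100)
  } else 0

  if (is.null(label)) label <- spec$waveform
  bsa_ts(t, osc + trend + eps, label = label)
}

# Canonical fixture catalogue. Each entry is a function(seed) -> sim_spec.
fixture_catalog <- function() {
  row_common <- function(e_a, e_p = 0, seed) {
    sim_spec(omega = 0.5, amp_noise_pct = e_a, phase_noise_pct = e_p,
             n_points = 100L, dt = 3, seed = seed)
  }
  list(
    table2_row1 = function(seed) row_common(1, seed = seed),
    table2_row2 = function(seed) row_common(10, seed = seed),
    table2_row3 = function(seed) row_common(40, seed = seed),
    table2_row4 = function(seed) row_common(10, 10, seed = seed),
    table2_row5 = function(seed) row_common(10, 40, seed = seed),
    table2_row6 = function(seed) row_common(100, 40, seed = seed),
    table2_row7 = function(seed) sim_spec(
      omega = c(0.3, 0.5), amp_noise_pct = 10, phase_noise_pct = 10,
      n_points = 100L, dt = 3, seed = seed),
    # trended rows: 200 points at 1 s so trend and tone stay comparable
    table2_row8 = function(seed) sim_spec(
      omega = 0.5, amp_noise_pct = 10, trend_coeffs = c(-0.05),
      n_points = 200L, dt = 1, seed = seed),
    table2_row9 = function(seed) sim_spec(
      omega = 0.5, amp_noise_pct = 10, trend_coeffs = c(0, -0.005),
      n_points = 200L, dt = 1, seed = seed),
    table2_row10 = function(seed) sim_spec(
      omega = 0.5, amp_noise_pct = 10, trend_coeffs = c(0, 0, -0.0005),
      n_points = 200L, dt = 1, seed = seed),
    table1_caseA = function(seed) row_common(10, seed = seed),
    table1_caseB = function(seed) sim_spec(
      omega = c(0.3, 0.5), amp_noise_pct = 10, n_points = 100L, dt = 3,
      seed = seed),
    fig1 = function(seed) row_common(10, seed = seed),
    fig2_chirp = function(seed) sim_spec(
      omega = c(0.25, 0.5), waveform = "chirp", n_points = 300L, dt = 1,
      seed = seed),
    fig3_switch = function(seed) sim_spec(
      omega = c(0.2, 0.4), waveform = "freq_switch", n_points = 600L,
      dt = 1, seed = seed),
    s1_trend = function(seed) sim_spec(
      omega = 0.5, amp_noise_pct = 10, trend_coeffs = c(0, -0.005),
      n_points = 200L, dt = 1, seed = seed),
    s2_short = function(seed) sim_spec(
      omega = 0.5, amp_noise_pct = 10, n_points = 20L, dt = 1, seed = seed),
    s3_harmonics = function(seed) sim_spec(
      omega = 0.1, waveform = "harmonic_stack", n_points = 200L, dt = 1,
      seed = seed),
    s4_two = function(seed) sim_spec(
      omega = c(0.3, 0.5), use_cos = TRUE, n_points = 250L, dt = 1,
      seed = seed),
    s5_close = function(seed) sim_spec(
      omega = c(0.498, 0.505), use_cos = TRUE, amp_noise_pct = 10,
      n_points = 600L, dt = 1, seed = seed)
  )
}

#' List the available canonical fixtures
#' @return Character vector of fixture names.
#' @export
fixture_names <- function() names(fixture_catalog())

#' Retrieve a canonical test fixture
#'
#' Returns the spec and a realisation of one of the catalogued synthetic
#' test signals (the harmonic test battery: noise levels 1-100%, phase
#' jitter, polynomial trends, two-tone and close-pair signals, harmonic
#' stacks, a frequency switch, a chirp, a 20-point short series).
#'
#' @param name A name from [fixture_names()].
#' @param seed Optional seed override (each fixture has a fixed default).
#' @return A list with `spec` (the [sim_spec()]) and `ts` (the realised
#'   [bsa_ts()]).
#' @export
bsa_fixture <- function(name, seed = NULL) {
  cat_ <- fixture_catalog()
  if (!name %in% names(cat_)) {
    bsa_stop("bsa_validation_error", sprintf(
      "unknown fixture '%s'; see fixture_names()", name))
  }
  default_seed <- 1000L + match(name, names(cat_))
  spec <- cat_[[name]](if (is.null(seed)) default_seed else as.integer(seed))
  list(spec = spec, ts = simulate_timeseries(spec, label = name))
}
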