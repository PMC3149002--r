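#' Periodogram of a uniformly sampled series
#'
#' Classical Fourier baseline: the squared modulus of the FFT of the
#' mean-removed data, normalised by the number of points, reported at the
#' positive Fourier frequencies `omega_k = 2*pi*k / (N*dt)`,
#' `k = 1..floor(N/2)`. The DC bin is excluded. Requires uniform sampling -
#' that restriction, which BSA does not share, is part of what the
#' comparison is about.
#'
#' @param ts A [bsa_ts()] with (numerically) uniform sampling.
#' @param demean Remove the mean before transforming (default `TRUE`;
#'   without it any trend or offset dominates the low-frequency bins).
#' @return An object of class `bsa_spectrum` with `omega` (rad/time,
#'   increasing) and `power`.
#' @export
periodogram <- function(ts, demean = TRUE) {
  stopifnot(inherits(ts, "bsa_ts"))
  dt <- check_uniform(ts)
  x <- ts$values
  if (demean) x <- x - mean(x)
  N <- length(x)
  X <- stats::fft(x)
  k <- seq_len(N %/% 2L)
  structure(list(omega = 2 * pi * k / (N * dt),
                 power = Mod(X[k + 1L])^2 / N,
                 N = N, dt = dt),
            class = "bsa_spectrum")
}

check_uniform <- function(ts) {
  dt <- diff(ts$times)
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
    bsa_stop("bsa_validation_error",
             "FFT-based methods require uniform sampling; this series is non-uniform (BSA has no such restriction)")
  }
  mean(dt)
}

#' @export
print.bsa_spectrum <- function(x, ...) {
  s <- fft_summary(x)
  cat(sprintf("<bsa_spectrum> %d bins, spacing %.4g rad/time; <omega> = %.4g, sigma_FFT = %.4g\n",
              length(x$omega), x$omega[2L] - x$omega[1L], s$omega_mean,
              s$sigma_fft))
  invisible(x)
}

#' Power-weighted summary of a spectrum
#'
#' Summarises the spectrum by the power-weighted mean frequency and the
#' power-weighted standard deviation `sigma_FFT`. These are the FFT-side
#' counterparts of the BSA posterior mode and `sigma_BSA`.
#'
#' @param spectrum A `bsa_spectrum` from [periodogram()].
#' @return A list with `omega_mean` and `sigma_fft`.
#' @export
fft_summary <- function(spectrum) {
  stopifnot(inherits(spectrum, "bsa_spectrum"))
  p <- spectrum$power
  tot <- sum(p)
  if (tot <= 0) bsa_stop("bsa_validation_error", "spectrum has zero total power")
  w <- p / tot
  mu <- sum(w * spectrum$omega)
  list(omega_mean = mu,
       sigma_fft = sqrt(max(0, sum(w * (spectrum$omega - mu)^2))))
}

#' Moving-average detrending
#'
#' Subtracts a centred moving average of odd width from the series; at the
#' edges the window shrinks to the available one-sided samples. This is the
#' standard pre-processing step Fourier analysis needs on trended traces
#' (BSA models the trend instead).
#'
#' @param ts A [bsa_ts()].
#' @param window_points Odd window width, `3 <= window < N`.
#' @return A detrended [bsa_ts()] of the same length.
#' @export
detrend_moving_average <- function(ts, window_points) {
  stopifnot(inherits(ts, "bsa_ts"))
  W <- as.integer(window_points)
  N <- length(ts$values)
  if (W %% 2L != 1L || W < 3L || W >= N) {
    bsa_stop("bsa_validation_error",
             "window must be odd and satisfy 3 <= window < N")
  }
  ma <- zoo::rollapply(zoo::zoo(ts$values), width = W, FUN = mean,
                       align = "center", partial = TRUE)
  bsa_ts(ts$times, ts$values - as.numeric(ma),
         label = paste0(ts$label, " (detrended)"))
}

#' Short-time Fourier transform power map
#'
#' Per-segment periodograms with a Hann taper, at hop
#' `window_points - overlap_points`, computed with [signal::specgram()].
#' The layout mirrors [bsal()]'s time-frequency map so the two can be
#' plotted side by side.
#'
#' @param ts A uniformly sampled [bsa_ts()].
#' @param window_points Segment length in samples.
#' @param overlap_points Overlap between consecutive segments
#'   (`< window_points`).
#' @return An object of class `bsa_stft` with `window_centers` (time),
#'   `omega` (rad/time, DC excluded) and `power`
#'   (windows x frequencies, `|FFT|^2 / window_points`).
#' @export
stft <- function(ts, window_points, overlap_points = 0L) {
  stopifnot(inherits(ts, "bsa_ts"))
  dt <- check_uniform(ts)
  W <- as.integer(window_points)
  ov <- as.integer(overlap_points)
  if (ov >= W) bsa_stop("bsa_validation_error", "overlap must be < window")
  if (W > length(ts$values)) {
    bsa_stop("bsa_size_error", "window longer than the series")
  }
  sg <- signal::specgram(ts$values, n = W, Fs = 1 / dt, window = W,
                         overlap = ov)
  omega <- 2 * pi * as.numeric(sg$f)
  keep <- omega > 0
  power <- t(Mod(sg$S)^2 / W)[, keep, drop = FALSE]
  # sg$t is the 1-based start sample over Fs; report true window centres
  centers <- ts$times[1L] + (as.numeric(sg$t) - dt) + (W - 1L) / 2 * dt
  structure(list(window_centers = centers,
                 omega = omega[keep], power = power,
                 window_points = W, overlap_points = ov),
            class = "bsa_stft")
}

#' @export
print.bsa_stft <- function(x, ...) {
  cat(sprintf("<bsa_stft> %d segments of %d points (overlap %d), %d frequency bins\n",
              length(x$window_centers), x$window_points, x$overlap_points,
              length(x$omega)))
  invisible(x)
}

# Peak prominence: height above the higher of the two bounding saddles.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[seq_len(p - 1L)]
    right <- x[seq.int(p + 1L, length(x))]
    higher_l <- which(left >= x[p])
    higher_r <- which(right >= x[p])
    sad_l <- if (length(higher_l) == 0L) min(left) else
      min(left[seq.int(max(higher_l), p - 1L)])
    sad_r <- if (length(higher_r) == 0L) min(right) else
      min(right[seq_len(min(higher_r))])
    x[p] - max(sad_l, sad_r)
  }, numeric(1))
}

#' Interspike intervals of an oscillatory trace
#'
#' Detects spikes as local maxima whose prominence (height above the
#' surrounding saddles) exceeds a threshold, and returns the successive
#' differences of the spike times. Interspike intervals characterise spike
#' trains directly in the time domain; multiple distinct intervals need not
#' imply multiple spectral frequencies.
#'
#' @param ts A [bsa_ts()].
#' @param min_prominence Prominence threshold in signal units; default
#'   `0.5 * (max - median)` of the trace.
#' @return A list of class `bsa_isi` with `spike_times`, `intervals` and
#'   `histogram` (a [hist()] object, or `NULL` when fewer than two spikes
#'   are found, in which case a warning is raised).
#' @export
interspike_intervals <- function(ts, min_prominence = NULL) {
  stopifnot(inherits(ts, "bsa_ts"))
  x <- ts$values
  n <- length(x)
  if (is.null(min_prominence)) {
    min_prominence <- 0.5 * (max(x) - stats::median(x))
  }
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  spikes <- if (length(cand) > 0L && min_prominence > 0) {
    cand[peak_prominence(x, cand) >= min_prominence]
  } else integer(0)
  if (length(spikes) < 2L) {
    bsa_warn("bsa_isi_warning", "fewer than 2 spikes detected; no intervals")
    return(structure(list(spike_times = ts$times[spikes],
                          intervals = numeric(0), histogram = NULL),
                     class = "bsa_isi"))
  }
  iv <- diff(ts$times[spikes])
  structure(list(spike_times = ts$times[spikes], intervals = iv,
                 histogram = graphics::hist(iv, plot = FALSE)),
            class = "bsa_isi")
}

#' @export
print.bsa_isi <- function(x, ...) {
  cat(sprintf("<bsa_isi> %d spikes, %d intervals%s\n",
              length(x$spike_times), length(x$intervals),
              if (length(x$intervals) > 0L) {
                sprintf(" (median %.4g time units)", stats::median(x$intervals))
              } else ""))
  invisible(x)
}

#' Export a spectrum as CSV
#' @param spectrum A `bsa_spectrum`.
#' @param path Output path; columns `omega`, `power`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(data.frame(omega = spectrum$omega, power = spectrum$power),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
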