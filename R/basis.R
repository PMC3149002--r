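#' Specify a BSA model
#'
#' A model is a linear combination of `m = m_s + m_g` functions of time:
#' `m_s = 2r` sinusoids (one sine and one cosine per distinct angular
#' frequency) for the signal, plus `m_g` Legendre polynomials for a slowly
#' varying background trend.
#'
#' @param n_freq Number `r` of distinct angular frequencies in the signal
#'   part (each contributes a sine and a cosine column).
#' @param background_order Maximum Legendre order of the background
#'   expansion: `-1` means no background at all, `n >= 0` includes orders
#'   `0..n` (`n + 1` functions). The constant term is order 0.
#' @return An object of class `bsa_model_spec`.
#' @examples
#' model_spec(1, background_order = 2)
#' @export
model_spec <- function(n_freq = 1L, background_order = -1L) {
  n_freq <- as.integer(n_freq)
  background_order <- as.integer(background_order)
  if (n_freq < 1L) bsa_stop("bsa_validation_error", "`n_freq` must be >= 1")
  if (background_order < -1L) {
    bsa_stop("bsa_validation_error", "`background_order` must be >= -1")
  }
  structure(list(n_freq = n_freq, background_order = background_order),
            class = "bsa_model_spec")
}

#' @export
print.bsa_model_spec <- function(x, ...) {
  bg <- if (x$background_order < 0L) "no background" else
    sprintf("Legendre background orders 0..%d", x$background_order)
  cat(sprintf("<bsa_model_spec> r = %d frequencies (%d sinusoid columns), %s; m = %d\n",
              x$n_freq, 2L * x$n_freq, bg, n_model_functions(x)))
  invisible(x)
}

#' Number of model functions of a spec
#' @param spec A [model_spec()].
#' @return Integer `m = 2 * n_freq + (background_order + 1)`.
#' @export
n_model_functions <- function(spec) {
  2L * spec$n_freq + (spec$background_order + 1L)
}

# Legendre polynomials P_0..P_n evaluated by the Bonnet recurrence
# (k+1) P_{k+1}(x) = (2k+1) x P_k(x) - k P_{k-1}(x), on x in [-1, 1].
# Returns a length(x) x (n+1) matrix.
legendre_matrix <- function(x, n) {
  out <- matrix(0, length(x), n + 1L)
  out[, 1L] <- 1
  if (n >= 1L) out[, 2L] <- x
  if (n >= 2L) {
    for (k in 1:(n - 1L)) {
      out[, k + 2L] <- ((2 * k + 1) * x * out[, k + 1L] - k * out[, k]) / (k + 1)
    }
  }
  out
}

#' Evaluate the model-function design matrix
#'
#' Columns are ordered `sin(w_1 t), cos(w_1 t), ..., sin(w_r t), cos(w_r t),
#' P_0(tau), ..., P_n(tau)` where `P_k` are Legendre polynomials and `tau`
#' maps the observed time span affinely onto `[-1, 1]`
#' (`tau = 2 (t - t_1) / (t_N - t_1) - 1`).
#'
#' @param spec A [model_spec()].
#' @param omega Numeric vector of length `spec$n_freq`, angular frequencies
#'   in rad per native time unit; positive and distinct.
#' @param times Numeric vector of sampling times.
#' @return An `N x m` numeric matrix with informative column names.
#' @export
make_design <- function(spec, omega, times) {
  stopifnot(inherits(spec, "bsa_model_spec"))
  r <- spec$n_freq
  if (length(omega) != r) {
    bsa_stop("bsa_validation_error", sprintf(
      "`omega` must have length %d (one per modelled frequency)", r))
  }
  if (any(omega <= 0)) bsa_stop("bsa_validation_error", "frequencies must be positive")
  if (anyDuplicated(omega)) {
    bsa_stop("bsa_degenerate_basis", "duplicate frequencies give a singular design")
  }
  N <- length(times)
  m <- n_model_functions(spec)
  if (m >= N) {
    bsa_stop("bsa_size_error", sprintf(
      "model has m = %d functions but only N = %d data points", m, N))
  }
  cols <- vector("list", m)
  nm <- character(m)
  for (k in seq_len(r)) {
    cols[[2L * k - 1L]] <- sin(omega[k] * times)
    cols[[2L * k]] <- cos(omega[k] * times)
    nm[2L * k - 1L] <- sprintf("sin_w%d", k)
    nm[2L * k] <- sprintf("cos_w%d", k)
  }
  if (spec$background_order >= 0L) {
    tau <- 2 * (times - times[1L]) / (times[N] - times[1L]) - 1
    P <- legendre_matrix(tau, spec$background_order)
    for (j in 0:spec$background_order) {
      cols[[2L * r + 1L + j]] <- P[, j + 1L]
      nm[2L * r + 1L + j] <- sprintf("legendre_%d", j)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  X
}

#' Orthonormalise a design matrix by Cholesky decomposition
#'
#' With Gram matrix `G = X'X = R'R` (R upper triangular, positive diagonal),
#' the returned basis is `H = X R^{-1}`, which satisfies `H'H = I` and spans
#' the same column space as `X`. The positive-diagonal convention makes `H`
#' deterministic.
#'
#' @param design An `N x m` full-column-rank matrix.
#' @return A list with `H` (orthonormal `N x m` matrix) and `chol_factor`
#'   (the upper-triangular factor `R`), class `bsa_orthobasis`.
#' @export
orthonormalize <- function(design) {
  design <- as.matrix(design)
  G <- crossprod(design)
  # Guard against near-degenerate bases: a silently regularised Gram matrix
  # would change every evidence value downstream, so we refuse instead.
  kap <- tryCatch(kappa(G, exact = TRUE), error = function(e) Inf)
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R) || kap > 1e12) {
    qrd <- qr(design)
    off <- if (qrd$rank < ncol(design)) {
      cn <- colnames(design)
      bad <- sort(qrd$pivot[seq.int(qrd$rank + 1L, ncol(design))])[1L]
      if (is.null(cn)) sprintf("column %d", bad) else sprintf("column '%s'", cn[bad])
    } else {
      sprintf("condition number %.3g", kap)
    }
    bsa_stop("bsa_degenerate_basis", sprintf(
      "design matrix is (numerically) rank deficient at %s", off))
  }
  H <- t(backsolve(R, t(design), transpose = TRUE))
  dimnames(H) <- dimnames(design)
  structure(list(H = H, chol_factor = R), class = "bsa_orthobasis")
}

#' Sufficient statistics of the marginal posterior
#'
#' Projects the data onto an orthonormal model basis. Everything the
#' marginal posterior of the frequencies needs is contained in the
#' projections `h_j = sum_i d_i H_j(t_i)`, their mean square
#' `h2_bar = mean(h_j^2)` and the mean square of the data
#' `d2_bar = mean(d_i^2)`. The quantity `N*d2_bar - m*h2_bar` equals the
#' least-squares residual sum of squares of the model fit.
#'
#' @param values Numeric data vector (or a [bsa_ts()]).
#' @param basis A `bsa_orthobasis` from [orthonormalize()], built on the
#'   same time points.
#' @return A list of class `bsa_suffstats` with `h`, `h2_bar`, `d2_bar`,
#'   `N`, `m`, `gram` and `chol_factor`.
#' @export
sufficient_stats <- function(values, basis) {
  if (inherits(values, "bsa_ts")) values <- values$values
  stopifnot(inherits(basis, "bsa_orthobasis"))
  H <- basis$H
  N <- nrow(H)
  m <- ncol(H)
  if (length(values) != N) {
    bsa_stop("bsa_size_error", "data length does not match the basis")
  }
  h <- drop(crossprod(H, values))
  structure(list(h = h,
                 h2_bar = sum(h^2) / m,
                 d2_bar = sum(values^2) / N,
                 N = N, m = m,
                 chol_factor = basis$chol_factor),
            class = "bsa_suffstats")
}

# One-shot internal path: design -> orthonormal basis -> stats at a given
# omega. Used by every posterior/evidence evaluation, so kept lean.
bsa_stats_at <- function(times, values, spec, omega) {
  X <- make_design(spec, omega, times)
  B <- orthonormalize(X)
  sufficient_stats(values, B)
}
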