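#' Nested-sampling configuration
#'
#' @param prior_box Support of the uniform frequency prior: either a vector
#'   `c(low, high)` applied to every component, or an `r x 2` matrix of
#'   per-component bounds (rad per time unit, positive).
#' @param n_live Number of live points (>= 50).
#' @param termination_frac Stop when the estimated evidence still held by
#'   the live set falls below this fraction of the accumulated evidence.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @return An object of class `bsa_ns_config`.
#' @export
ns_config <- function(prior_box = c(0.05, 1.5), n_live = 400L,
                      termination_frac = 1e-3, seed = 1L) {
  if (is.vector(prior_box)) prior_box <- matrix(prior_box, 1L, 2L)
  if (ncol(prior_box) != 2L || any(prior_box <= 0) ||
      any(prior_box[, 1L] >= prior_box[, 2L])) {
    bsa_stop("bsa_validation_error",
             "prior_box must hold positive bounds with low < high")
  }
  if (n_live < 50L) bsa_stop("bsa_validation_error", "n_live must be >= 50")
  if (!(termination_frac > 0 && termination_frac < 0.1)) {
    bsa_stop("bsa_validation_error", "termination_frac must be in (0, 0.1)")
  }
  structure(list(prior_box = prior_box, n_live = as.integer(n_live),
                 termination_frac = termination_frac, seed = as.integer(seed)),
            class = "bsa_ns_config")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run a generic nested-sampling loop over a box with uniform prior.
# loglik must accept a numeric vector of length r and return a scalar
# (possibly -Inf). Returns raw log-evidence of integral(L * prior).
ns_loop <- function(loglik, box, n_live, termination_frac, max_iter = 200000L) {
  r <- nrow(box)
  lo <- box[, 1L]
  wid <- box[, 2L] - box[, 1L]
  draw_prior <- function() lo + stats::runif(r) * wid

  live <- matrix(0, n_live, r)
  liveL <- numeric(n_live)
  for (i in seq_len(n_live)) {
    live[i, ] <- draw_prior()
    liveL[i] <- loglik(live[i, ])
  }

  dead <- matrix(0, max_iter, r)
  deadL <- numeric(max_iter)
  logw <- numeric(max_iter)
  logZ <- -Inf
  n_calls <- n_live
  use_mcmc <- FALSE
  step_scale <- wid / 10

  for (it in seq_len(max_iter)) {
    worst <- which.min(liveL)
    Lmin <- liveL[worst]
    # likelihood plateau (e.g. the capped perfect-fit value): no constrained
    # draw can strictly improve, and no evidence remains to resolve
    if (max(liveL) - Lmin < 1e-12) {
      it <- it - 1L
      break
    }
    # trapezoid prior-mass shrinkage, X_i = exp(-i / n_live):
    # w_i = (X_{i-1} - X_{i+1}) / 2
    logw_i <- log(0.5) - (it - 1L) / n_live + log1p(-exp(-2 / n_live))
    dead[it, ] <- live[worst, ]
    deadL[it] <- Lmin
    logw[it] <- logw_i
    logZ <- logsumexp(c(logZ, logw_i + Lmin))

    # replacement draw constrained to L > Lmin
    found <- FALSE
    if (!use_mcmc) {
      for (try in 1:100) {
        cand <- draw_prior()
        cl <- loglik(cand)
        n_calls <- n_calls + 1L
        if (cl > Lmin) {
          live[worst, ] <- cand
          liveL[worst] <- cl
          found <- TRUE
          break
        }
      }
      if (!found) {
        use_mcmc <- TRUE
        step_scale <- pmax(2 * apply(live, 2L, stats::sd), wid * 1e-12)
      }
    }
    if (!found) {
      src <- sample.int(n_live, 1L)
      if (src == worst) src <- if (worst == n_live) 1L else worst + 1L
      cur <- live[src, ]
      curL <- liveL[src]
      acc <- 0L
      n_try <- 0L
      for (step in 1:25) {
        cand <- cur + stats::rnorm(r) * step_scale
        n_try <- n_try + 1L
        if (any(cand < lo) || any(cand > lo + wid)) next
        cl <- loglik(cand)
        n_calls <- n_calls + 1L
        if (cl > Lmin) {
          cur <- cand
          curL <- cl
          acc <- acc + 1L
          if (acc >= 12L) break  # decorrelated from the start point
        }
      }
      # keep the within-contour acceptance rate near one half
      step_scale <- if (acc * 2L > n_try) step_scale * 1.5 else step_scale * 0.6
      if (curL <= Lmin) {
        # walk never escaped the contour: copy any strictly better live point
        better <- which(liveL > Lmin)
        if (length(better) == 0L) {
          bsa_stop("bsa_ns_error",
                   "failed to draw a constrained replacement point")
        }
        src2 <- better[sample.int(length(better), 1L)]
        cur <- live[src2, ]
        curL <- liveL[src2]
      }
      live[worst, ] <- cur
      liveL[worst] <- curL
    }

    # termination: remaining evidence bounded by max live L times X_i
    logX <- -it / n_live
    remain <- max(liveL) + logX
    if (remain < logZ + log(termination_frac) && it > n_live) break
  }

  # fold in the final live set, each carrying X_final / n_live of prior mass
  logX <- -it / n_live
  lw_live <- logX - log(n_live)
  logZ <- logsumexp(c(logZ, lw_live + liveL))
  dead <- rbind(dead[seq_len(it), , drop = FALSE], live)
  deadL <- c(deadL[seq_len(it)], liveL)
  logw <- c(logw[seq_len(it)], rep(lw_live, n_live))

  lpost <- logw + deadL - logZ
  w <- exp(lpost - logsumexp(lpost))
  H <- sum(w[w > 0] * (deadL[w > 0] - logZ))
  list(logZ = logZ, H = max(H, 0), samples = dead, weights = w,
       n_iter = it, n_calls = n_calls)
}

#' Nested sampling of the frequency posterior
#'
#' Computes the evidence and weighted posterior samples of the
#' amplitude/noise-marginalised posterior over the frequency box. The
#' marginalised form keeps the sampled dimension equal to the number of
#' frequencies `r`. Replacement points are drawn by rejection from the box
#' while that is efficient, then by a likelihood-constrained random walk
#' started from a random live point.
#'
#' With `priors` supplied, the returned `log_evidence` is the full model
#' evidence (amplitude-prior occupancy and noise-prior normalisation
#' included) and is directly comparable with [laplace_log_evidence()] under
#' the same priors. Without `priors` it is the integral of the bare
#' unnormalised posterior over the box, which is sufficient for posterior
#' summaries.
#'
#' @param ts A [bsa_ts()].
#' @param spec A [model_spec()].
#' @param cfg A [ns_config()]; its `prior_box` is recycled to
#'   `spec$n_freq` components if given as a single `(low, high)` pair.
#' @param priors Optional [evidence_priors()] for absolute evidence values.
#' @return An object of class `bsa_ns` with `log_evidence`,
#'   `log_evidence_err`, `samples` (matrix with one column per frequency
#'   plus a `weight` column; components sorted ascending within each draw),
#'   `omega_mean`, `omega_sd`, `information`, `n_calls` and `method`.
#' @export
nested_sample <- function(ts, spec, cfg = ns_config(), priors = NULL) {
  stopifnot(inherits(ts, "bsa_ts"), inherits(spec, "bsa_model_spec"),
            inherits(cfg, "bsa_ns_config"))
  r <- spec$n_freq
  box <- cfg$prior_box
  if (nrow(box) == 1L && r > 1L) box <- box[rep(1L, r), , drop = FALSE]
  if (nrow(box) != r) {
    bsa_stop("bsa_validation_error", "prior_box rows must match n_freq")
  }

  loglik <- function(w) {
    lp <- tryCatch(log_posterior(ts, spec, w), bsa_error = function(e) NA_real_)
    if (is.na(lp)) -Inf else lp
  }

  # seed locally without clobbering the caller's RNG stream
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
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  run <- ns_loop(loglik, box, cfg$n_live, cfg$termination_frac)

  logZ <- run$logZ
  if (!is.null(priors)) {
    N <- length(ts$values)
    m <- n_model_functions(spec)
    d2_bar <- mean(ts$values^2)
    logZ <- logZ + evidence_const_offset(N, m, d2_bar, priors)
  }
  err <- sqrt(run$H / cfg$n_live)

  # sort components within each draw: the posterior is exchangeable in the
  # frequency labels, so summaries are taken on the ordered tuple
  samp <- t(apply(run$samples, 1L, sort))
  if (r == 1L) samp <- matrix(run$samples, ncol = 1L)
  w <- run$weights
  mu <- colSums(samp * w)
  sd <- sqrt(pmax(0, colSums(samp^2 * w) - mu^2))

  structure(list(
    log_evidence = logZ, log_evidence_err = err,
    samples = cbind(samp, weight = w),
    omega_mean = mu, omega_sd = sd,
    information = run$H, n_iter = run$n_iter, n_calls = run$n_calls,
    method = "nested", priors = priors, seed = cfg$seed,
    data_id = data_fingerprint(ts), spec = spec),
    class = "bsa_ns")
}

#' @export
print.bsa_ns <- function(x, ...) {
  cat(sprintf("<bsa_ns> logZ = %.3f +/- %.3f (H = %.2f nats, %d calls)\n",
              x$log_evidence, x$log_evidence_err, x$information, x$n_calls))
  cat(sprintf("  omega_mean = %s, omega_sd = %s\n",
              paste(signif(x$omega_mean, 6), collapse = ", "),
              paste(signif(x$omega_sd, 3), collapse = ", ")))
  invisible(x)
}

#' Export weighted posterior samples as CSV
#' @param ns A `bsa_ns` result.
#' @param path Output path; columns `omega_1..omega_r`, `weight`.
#' @return `path`, invisibly.
#' @export
write_ns_samples <- function(ns, path) {
  df <- as.data.frame(ns$samples)
  r <- ncol(df) - 1L
  names(df) <- c(paste0("omega_", seq_len(r)), "weight")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

data_fingerprint <- function(ts) {
  c(N = length(ts$times), tsum = sum(ts$times), vsum = sum(ts$values),
    vss = sum(ts$values^2))
}
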