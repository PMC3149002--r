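#' Prior bounds entering the model evidence
#'
#' The evidence of a model depends on the normalisation of the priors of
#' its nuisance parameters. Amplitudes (in the orthonormalised basis) carry
#' a uniform prior over `[-delta_hi, delta_hi]`; the noise scale carries a
#' bounded Jeffreys prior over `sigma_bounds`; frequencies are uniform over
#' `gamma_bounds` (the scanned window). Defaults are scale-aware - they are
#' expressed in units of the RMS of the data - and *shared* across every
#' model compared on the same trace, so all common normalisation constants
#' cancel exactly in evidence ratios. What does not cancel is the Occam
#' penalty: each additional model function multiplies the evidence by
#' roughly `sqrt(2*pi*sigma_hat^2) / (2*delta_hi)`, and each additional
#' frequency by the reciprocal width of `gamma_bounds`.
#'
#' @param ts A [bsa_ts()] (used only for its RMS), or `NULL` if `rms` given.
#' @param gamma_bounds Frequency prior window `c(low, high)`, rad/time.
#' @param delta_rel Amplitude bound relative to the data RMS.
#' @param sigma_rel Noise-scale bounds relative to the data RMS.
#' @param rms Override for the data RMS.
#' @return An object of class `bsa_evidence_priors`.
#' @export
evidence_priors <- function(ts = NULL, gamma_bounds = c(0.05, 1.5),
                            delta_rel = c(0.01, 100),
                            sigma_rel = c(0.001, 10), rms = NULL) {
  if (is.null(rms)) {
    stopifnot(inherits(ts, "bsa_ts"))
    rms <- sqrt(mean(ts$values^2))
  }
  if (!(gamma_bounds[1L] > 0 && gamma_bounds[2L] > gamma_bounds[1L])) {
    bsa_stop("bsa_validation_error", "gamma_bounds must satisfy 0 < low < high")
  }
  structure(list(delta_bounds = delta_rel * rms,
                 gamma_bounds = gamma_bounds,
                 sigma_bounds = sigma_rel * rms,
                 rms = rms),
            class = "bsa_evidence_priors")
}

priors_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

# Constant (omega-independent) part of the full marginal log-likelihood,
# relative to the bare unnormalised posterior log_posterior():
#   l_ev(omega) - log_posterior(omega)
# where, after integrating the m orthonormal amplitudes (uniform over
# +/- delta_hi) and the noise scale (bounded Jeffreys) out of the Gaussian
# likelihood,
#   l_ev(omega) = -((N-m)/2) log(2 pi) + log(Gamma((N-m)/2)/2)
#                 + ((N-m)/2) log 2 - ((N-m)/2) log Qmin(omega)
#                 - m log(2 delta_hi) - log log(R_sigma)
# and log_posterior(omega) = -((N-m)/2) [log Qmin(omega) - log(N d2_bar)].
evidence_const_offset <- function(N, m, d2_bar, priors) {
  delta_hi <- priors$delta_bounds[2L]
  R_sigma <- priors$sigma_bounds[2L] / priors$sigma_bounds[1L]
  k <- (N - m) / 2
  -k * log(2 * pi) + lgamma(k) - log(2) + k * log(2) -
    m * log(2 * delta_hi) - log(log(R_sigma)) -
    k * log(N * d2_bar)
}

# Central finite-difference Hessian of f at x, steps per component.
fd_hessian <- function(f, x, step) {
  r <- length(x)
  H <- matrix(0, r, r)
  f0 <- f(x)
  for (i in seq_len(r)) {
    ei <- replace(numeric(r), i, step[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step[i]^2
    if (i < r) for (j in (i + 1L):r) {
      ej <- replace(numeric(r), j, step[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * step[i] * step[j])
    }
  }
  H
}

#' Laplace-approximation model evidence
#'
#' Locates the posterior mode of the frequencies (coarse scan plus
#' Nelder-Mead for a single frequency; Nelder-Mead from `omega_start` for
#' more), verifies unimodality, and expands the amplitude/noise-marginalised
#' log-likelihood to second order around the mode. The Hessian is computed
#' by central finite differences and orthogonalised (eigendecomposition);
#' all curvature directions must decrease the captured power, otherwise the
#' expansion is invalid and the function refuses, directing the caller to
#' [nested_sample()]. Frequency-label exchange symmetry is accounted for
#' with a `log(r!)` multiplicity term.
#'
#' @param ts A [bsa_ts()].
#' @param spec A [model_spec()].
#' @param priors An [evidence_priors()]; its `gamma_bounds` set the scan
#'   window and the uniform frequency prior.
#' @param omega_start Optional starting tuple (required for `n_freq > 1`).
#' @param n_grid Coarse scan resolution.
#' @return An object of class `bsa_evidence` with `log_evidence` (nats),
#'   `method = "laplace"`, `err = 0`, `mode`, `hessian_logdet` and the
#'   priors used.
#' @export
laplace_log_evidence <- function(ts, spec, priors, omega_start = NULL,
                                 n_grid = 300L) {
  stopifnot(inherits(priors, "bsa_evidence_priors"))
  r <- spec$n_freq
  gb <- priors$gamma_bounds
  if (is.null(omega_start)) {
    if (r != 1L) {
      bsa_stop("bsa_validation_error",
               "omega_start is required for multi-frequency Laplace evidence")
    }
    sc <- bsa_scan(ts, spec, gb[1L], gb[2L], n_grid)
    # multimodality screen on the coarse grid
    dens <- exp(sc$log_post - max(sc$log_post, na.rm = TRUE))
    dens[is.na(dens)] <- 0
    if (count_modes_1d(dens) > 1L) {
      bsa_stop("bsa_multimodal_error", paste(
        "posterior is multimodal over the scan window;",
        "the Laplace expansion is ill-suited - use nested_sample()"))
    }
    omega_start <- sc$mode
  }
  step_hint <- (gb[2L] - gb[1L]) / n_grid
  mode <- refine_peak(ts, spec, omega_start, step_hint = step_hint)
  fs <- fine_sample(ts, spec, mode, half_width = 0.02, n_fine = 101L)
  if (fs$multimodal) {
    bsa_stop("bsa_multimodal_error", paste(
      "posterior is multimodal near the mode;",
      "the Laplace expansion is ill-suited - use nested_sample()"))
  }

  lp <- function(w) {
    v <- tryCatch(log_posterior(ts, spec, w), bsa_error = function(e) NA_real_)
    if (is.na(v)) -Inf else v
  }
  step <- pmax(1e-6, 1e-4 * abs(mode))
  Hm <- fd_hessian(lp, mode, step)
  if (any(!is.finite(Hm))) {
    bsa_stop("bsa_multimodal_error", paste(
      "curvature is not estimable at the located mode;",
      "use nested_sample()"))
  }
  eig <- eigen(Hm, symmetric = TRUE)
  if (any(eig$values >= 0)) {
    bsa_stop("bsa_multimodal_error", paste(
      "curvature at the located mode is not negative definite;",
      "use nested_sample()"))
  }
  hess_logdet <- sum(log(-eig$values))

  N <- length(ts$values)
  m <- n_model_functions(spec)
  d2_bar <- mean(ts$values^2)
  logZ <- lp(mode) +
    evidence_const_offset(N, m, d2_bar, priors) +
    (r / 2) * log(2 * pi) - 0.5 * hess_logdet +
    lfactorial(r) - sum(log(rep(gb[2L] - gb[1L], r)))

  structure(list(log_evidence = logZ, method = "laplace", err = 0,
                 mode = mode, hessian_logdet = hess_logdet,
                 priors = priors, spec = spec,
                 data_id = data_fingerprint(ts)),
            class = "bsa_evidence")
}

#' @export
print.bsa_evidence <- function(x, ...) {
  cat(sprintf("<bsa_evidence> logZ = %.3f nats (%s), mode = %s\n",
              x$log_evidence, x$method,
              paste(signif(x$mode, 6), collapse = ", ")))
  invisible(x)
}

#' Posterior ratio of two models
#'
#' With equal model priors the posterior ratio of two models is the ratio
#' of their evidences. Both evidences must have been computed on the same
#' data under identical prior bounds, otherwise the shared normalisation
#' constants would not cancel and the ratio would be meaningless; this is
#' checked and enforced.
#'
#' @param ev_a,ev_b `bsa_evidence` or `bsa_ns` results.
#' @return A list with `ratio` and `log_ratio`.
#' @export
posterior_ratio <- function(ev_a, ev_b) {
  if (!priors_equal(ev_a$priors, ev_b$priors)) {
    bsa_stop("bsa_validation_error",
             "evidences were computed under different priors; ratio undefined")
  }
  if (!isTRUE(all.equal(ev_a$data_id, ev_b$data_id))) {
    bsa_stop("bsa_validation_error",
             "evidences were computed on different data; ratio undefined")
  }
  lr <- ev_a$log_evidence - ev_b$log_evidence
  list(ratio = exp(lr), log_ratio = lr)
}

# Evidence with automatic fallback: Laplace where the posterior is unimodal,
# Nested Sampling otherwise (or always, for multi-frequency models).
evidence_auto <- function(ts, spec, priors, ns_fallback = TRUE,
                          n_live = 300L, seed = 1L, n_grid = 300L) {
  if (spec$n_freq == 1L) {
    ev <- tryCatch(
      laplace_log_evidence(ts, spec, priors, n_grid = n_grid),
      bsa_multimodal_error = function(e) NULL)
    if (!is.null(ev)) return(ev)
    if (!ns_fallback) {
      bsa_stop("bsa_multimodal_error",
               "posterior multimodal and ns_fallback = FALSE")
    }
  }
  cfg <- ns_config(prior_box = priors$gamma_bounds, n_live = n_live,
                   seed = seed)
  nested_sample(ts, spec, cfg, priors = priors)
}

#' Automated selection of the background expansion order
#'
#' Walks the model ladder `no background, order 0, order 1, ...` computing
#' the evidence ratio of each model to the next richer one. The first ratio
#' above 1 stops the walk: the simpler model is preferred and its order is
#' returned, together with the full ratio trace. The walk is greedy - it
#' stops at the first local winner and is not guaranteed to find the global
#' optimum over all orders - so the result carries `status = "local"`.
#'
#' @param ts A [bsa_ts()].
#' @param base_spec A [model_spec()] fixing the number of frequencies; its
#'   `background_order` is ignored.
#' @param max_order Largest Legendre order to consider.
#' @param priors An [evidence_priors()] shared by every model on the ladder;
#'   defaults to [evidence_priors()] of `ts`.
#' @param ns_fallback Use [nested_sample()] when a posterior is multimodal.
#' @param n_live Live points for any Nested-Sampling fallback runs.
#' @param seed Seed for any Nested-Sampling fallback runs.
#' @return A list of class `bsa_order_selection`: `selected` (the order, or
#'   `max_order` with `converged = FALSE` when no ratio exceeded 1),
#'   `trace` (data frame of models and ratios), `evidences`, `converged`,
#'   `status`.
#' @export
select_background_order <- function(ts, base_spec = model_spec(1L),
                                    max_order = 6L, priors = NULL,
                                    ns_fallback = TRUE, n_live = 300L,
                                    seed = 1L) {
  if (max_order < 0L) bsa_stop("bsa_validation_error", "max_order must be >= 0")
  if (is.null(priors)) priors <- evidence_priors(ts)
  orders <- seq.int(-1L, max_order)
  evs <- vector("list", length(orders))
  names(evs) <- as.character(orders)
  get_ev <- function(i) {
    if (is.null(evs[[i]])) {
      spec <- model_spec(base_spec$n_freq, orders[i])
      evs[[i]] <<- evidence_auto(ts, spec, priors, ns_fallback,
                                 n_live = n_live, seed = seed)
    }
    evs[[i]]
  }
  trace <- data.frame(models = character(0), ratio = numeric(0),
                      log_ratio = numeric(0))
  selected <- max_order
  converged <- FALSE
  for (i in seq_len(length(orders) - 1L)) {
    pr <- posterior_ratio(get_ev(i), get_ev(i + 1L))
    trace <- rbind(trace, data.frame(
      models = sprintf("H_%dz/H_%dz", orders[i], orders[i + 1L]),
      ratio = pr$ratio, log_ratio = pr$log_ratio))
    if (pr$ratio > 1) {
      selected <- orders[i]
      converged <- TRUE
      break
    }
  }
  structure(list(selected = selected, trace = trace,
                 evidences = evs[!vapply(evs, is.null, logical(1))],
                 converged = converged, status = "local", priors = priors),
            class = "bsa_order_selection")
}

#' @export
print.bsa_order_selection <- function(x, ...) {
  cat(sprintf("<bsa_order_selection> selected background order: %d%s\n",
              x$selected, if (x$converged) "" else " (not converged)"))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Automated selection of the number of frequencies
#'
#' Same greedy ladder as [select_background_order()], over models with
#' `r = 1, 2, ...` frequencies at a fixed background order. Multi-frequency
#' evidences (and any multimodal single-frequency posterior) are computed
#' by Nested Sampling, since their posteriors are not unimodal in general.
#'
#' @param ts A [bsa_ts()].
#' @param background_order Background order shared by all models.
#' @param max_r Largest number of frequencies to consider.
#' @param priors Shared [evidence_priors()].
#' @param ns_fallback Permit Nested Sampling (required for `max_r > 1`).
#' @param n_live Live points for Nested-Sampling evidences.
#' @param seed Seed for the Nested-Sampling runs.
#' @return A list of class `bsa_freq_selection` with `selected`, `trace`,
#'   `evidences`, `converged`, `status` and `low_evidence` (flag set when
#'   even the selected model's absolute evidence is poor, e.g. pure noise).
#' @export
select_num_frequencies <- function(ts, background_order = -1L, max_r = 3L,
                                   priors = NULL, ns_fallback = TRUE,
                                   n_live = 300L, seed = 1L) {
  if (max_r < 1L) bsa_stop("bsa_validation_error", "max_r must be >= 1")
  if (is.null(priors)) priors <- evidence_priors(ts)
  evs <- vector("list", max_r + 1L)
  get_ev <- function(r) {
    if (is.null(evs[[r]])) {
      spec <- model_spec(r, background_order)
      evs[[r]] <<- if (r == 1L) {
        evidence_auto(ts, spec, priors, ns_fallback, n_live = n_live,
                      seed = seed)
      } else {
        cfg <- ns_config(prior_box = priors$gamma_bounds, n_live = n_live,
                         seed = seed + r)
        nested_sample(ts, spec, cfg, priors = priors)
      }
    }
    evs[[r]]
  }
  trace <- data.frame(models = character(0), ratio = numeric(0),
                      log_ratio = numeric(0))
  selected <- max_r
  converged <- FALSE
  for (r in seq_len(max_r)) {
    pr <- posterior_ratio(get_ev(r), get_ev(r + 1L))
    trace <- rbind(trace, data.frame(
      models = sprintf("H_%dw/H_%dw", r, r + 1L),
      ratio = pr$ratio, log_ratio = pr$log_ratio))
    if (pr$ratio > 1) {
      selected <- r
      converged <- TRUE
      break
    }
  }
  # a "winning" model can still explain the data poorly (pure noise):
  # compare its evidence with the no-signal residual benchmark
  sel_ev <- get_ev(selected)
  low_evidence <- is.finite(sel_ev$log_evidence) &&
    best_fit_gain(ts, model_spec(selected, background_order),
                  sel_ev$mode %||% sel_ev$omega_mean) < 3
  structure(list(selected = selected, trace = trace,
                 evidences = evs[!vapply(evs, is.null, logical(1))],
                 converged = converged, status = "local",
                 low_evidence = low_evidence, priors = priors),
            class = "bsa_freq_selection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Log-posterior height of the best fit over a flat (no-signal) posterior:
# small values mean no frequency stands out of the noise.
best_fit_gain <- function(ts, spec, mode) {
  tryCatch(log_posterior(ts, spec, mode), bsa_error = function(e) 0)
}

#' @export
print.bsa_freq_selection <- function(x, ...) {
  cat(sprintf("<bsa_freq_selection> selected r = %d frequencies%s%s\n",
              x$selected, if (x$converged) "" else " (not converged)",
              if (x$low_evidence) " [low evidence: no clear signal]" else ""))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Write a model-ratio trace as a two-column CSV
#' @param selection A `bsa_order_selection` or `bsa_freq_selection`.
#' @param path Output path; columns `models`, `ratio`.
#' @return `path`, invisibly.
#' @export
write_ratio_trace <- function(selection, path) {
  utils::write.csv(selection$trace[, c("models", "ratio")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
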