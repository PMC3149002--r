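# bsafreq

Bayesian spectrum analysis (BSA) for the time series biology actually
produces: short records, substantial noise, slow background trends and
sometimes non-uniform sampling — calcium spiking in root cells during
symbiotic signalling, circadian gene expression followed for a couple of
cycles, and simulated benchmarks of both. Instead of transforming the data,
`bsafreq` computes the posterior distribution of the angular frequency
itself, so every estimate arrives with its own uncertainty and every
modelling choice can be judged by its evidence.

## The model

A trace is modelled as sinusoids plus a polynomial background plus
Gaussian noise,

    d(t_i) = sum_k [ a_k sin(w_k t_i) + b_k cos(w_k t_i) ]
           + sum_j c_j P_j(tau_i) + e(t_i),

with Legendre polynomials `P_j` on the rescaled time domain as the
background family. The model functions are orthonormalised over the actual
sample times (Cholesky), and amplitudes and noise level are integrated out
analytically — uniform priors on amplitudes and frequencies, Jeffreys prior
on the noise scale — leaving the marginal posterior

    P(w | D, H, I)  ∝  [ 1 − m·h²_bar / (N·d²_bar) ]^((m−N)/2),

where `h_j` are the projections of the data onto the orthonormal model
functions. On top of that core the package provides:

- **automated model development**: the Legendre expansion order and the
  number of frequencies are chosen by evidence ratios (Laplace
  approximation at unimodal posteriors, Nested Sampling otherwise),
- **BSAL**, a sliding-window variant that tracks time-varying frequencies
  with windows as short as a third of a period,
- **classical comparators** — periodogram, power-weighted FFT summary,
  moving-average detrending, Hann-tapered STFT, interspike intervals,
- **a seeded simulator** regenerating the whole battery of benchmark
  signals (noise/phase-jitter levels, trends, two-tone and close-pair
  signals, harmonic stacks, frequency switches, chirps).

## A worked example

A unit sine at 0.5 rad/s, 10% additive noise, 100 points at 3 s spacing —
and what BSA reports on it:

```r
library(bsafreq)
ts  <- simulate_timeseries(sim_spec(omega = 0.5, amp_noise_pct = 10,
                                    n_points = 100, dt = 3, seed = 1001))
fit <- bsa(ts, model_spec(1))
fit
#> <bsa_posterior> 'harmonic'
#>   mode:   omega = 0.500097 rad/time  (period 12.5639)
#>   sigma_BSA = 0.000185 rad/time
#>   noise sigma = 0.113, snr = 6.1
```

The mode lands on the generating frequency to four decimals; `sigma_BSA`
(the sd of the normalised posterior) is ~1e-4 rad/s — two orders of
magnitude below the power-weighted spread of the periodogram of the same
data — the noise estimate recovers the generating 10% level, and the
signal-to-noise ratio is the RMS of the fitted sinusoid over that noise.

The automated pipeline makes the modelling decisions itself and logs each
evidence ratio. On a sinusoid carrying a strong quadratic trend:

```r
trended <- bsa_fixture("s1_trend")$ts    # sin(0.5 t) − 0.005 t² + 10% noise
sel <- select_background_order(trended, max_order = 6)
sel
#> <bsa_order_selection> selected background order: 2
#>      models         ratio  log_ratio
#>  H_-1z/H_0z  3.868365e-36  -81.54023
#>   H_0z/H_1z 3.844772e-118 -270.35833
#>   H_1z/H_2z  0.000000e+00 -964.43119
#>   H_2z/H_3z  5.092166e+04   10.83804
```

Ratios below 1 mean "the richer model wins"; the ladder stops at the first
ratio above 1, here selecting expansion order two — exactly the order of
the generating trend. A raw periodogram of the same trace puts its
power-weighted mean frequency near zero; BSA with the selected background
recovers 0.5 rad/s to within 0.01.

Two tones 0.007 rad/s apart (0.498 and 0.505), closer than one Fourier bin
at 600 points:

```r
close <- bsa_fixture("s5_close")$ts
ns <- nested_sample(close, model_spec(2), ns_config(c(0.3, 0.7), seed = 3))
ns$omega_mean
#> [1] 0.4979 0.5051
```

The front end `inst/scripts/bsafreq` exposes the same pipeline as
`bsafreq analyze|compare|bsal|simulate` for shell use.

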