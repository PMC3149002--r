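---
title: "Bayesian spectrum analysis of biological time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian spectrum analysis of biological time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsafreq)
```

## The problem

Biological oscillations - calcium spiking in root cells responding to
symbiotic signals, circadian gene expression followed for only two cycles -
produce short, noisy traces riding on slow trends (photobleaching, cell
movement, baseline drift), often sampled non-uniformly. The discrete
Fourier transform struggles under exactly these conditions: its frequency
resolution is fixed at $2\pi/(N\Delta t)$, it requires uniform sampling,
trends leak power across the whole spectrum, and it attaches no uncertainty
to its output. `bsafreq` implements the Bayesian alternative: treat the
angular frequency $\omega$ as the parameter of interest in an explicit data
model and compute its posterior distribution, with everything else
integrated out.

## The model and the marginal posterior

A trace $D = \{d(t_1),\dots,d(t_N)\}$ is modelled as signal plus background
plus noise,

$$d(t_i) = \sum_{j=1}^{m_s} a_j\,\psi_j(t_i;\omega)
         + \sum_{k=1}^{m_g} b_k\,\zeta_k(t_i) + e(t_i),$$

with one sine and one cosine per frequency ($m_s = 2r$) and Legendre
polynomials $P_0,\dots,P_n$ on the affinely mapped time domain
$\tau \in [-1,1]$ as the background family ($m_g = n+1$). The $m = m_s+m_g$
model functions are orthonormalised over the actual sample times by
Cholesky decomposition of their Gram matrix, so non-uniform grids need no
special treatment. Gaussian noise of unknown power $\sigma^2$ (the
maximum-entropy choice for a known power), uniform priors on the amplitudes
and frequencies and a Jeffreys prior on $\sigma$ give, after integrating
amplitudes and noise analytically, the marginal posterior

$$P(\boldsymbol\omega \mid D, H, I) \propto
  \left[1 - \frac{m\,\overline{h^2}}{N\,\overline{d^2}}\right]^{(m-N)/2},$$

where $h_j$ is the projection of the data onto the $j$-th orthonormal model
function, $\overline{h^2}$ their mean square and $\overline{d^2}$ the mean
square of the data. The bracketed fraction is the share of the data power
the model captures at this $\omega$; $N\overline{d^2} - m\overline{h^2}$
equals the least-squares residual, an identity the test suite verifies
against `lm.fit`. All arithmetic is done in log space through
`log1p`, because the exponent $(m-N)/2$ underflows the raw form for
$N \gtrsim 100$. A numerically perfect fit (captured share
indistinguishable from 1) is reported at the finite cap
$\frac{N-m}{2}\log(1/\varepsilon_{\mathrm{machine}})$.

Because this reconstruction of the marginal posterior is the heart of the
package, it is validated against an independent oracle: Simpson quadrature
of the explicit Gaussian likelihood over the amplitudes (of a
QR-orthonormalised basis) and the noise scale reproduces
`log_posterior()` up to one global constant to better than $10^{-3}$ on
small instances. Note that the amplitude integral must be taken in the
orthonormalised coordinates; integrating over raw sine/cosine coefficients
leaves an $\omega$-dependent Jacobian $\sqrt{\det\Phi}$ that does not
belong to this posterior form.

## Locating and summarising the peak

`bsa()` chains the stages: a coarse scan over a user-chosen window
(default $(0.05, 1.5]$ rad per time unit, 300 points), Nelder-Mead
refinement started from the grid mode with an initial simplex of two grid
steps, and fine sampling of the normalised density around the peak.
`sigma_BSA` is the standard deviation of that density - not of a Gaussian
fit, so no Gaussianity is asserted. The fine window widens (up to three
times) if more than 1% of the mass touches an edge and contracts when the
posterior turns out much sharper than the window, so the reported sd is
always resolved by the grid. Local maxima above 1% of the peak are counted;
more than one raises the multimodal flag, which routes evidence
computations to nested sampling. Two numerical details worth recording:
`optim()`'s Nelder-Mead `abstol` is a reach-zero criterion that terminates
immediately on negative objectives, so refinement uses `reltol` (plus a
restart and, in one dimension, a golden-section polish); and coarse-grid
ties are broken toward the lower frequency for determinism.

The noise estimate is the posterior-expected power
$\hat\sigma^2 = (N\overline{d^2} - m\overline{h^2})/(N-m-2)$ at the mode.
The signal-to-noise ratio divides the RMS of the *sinusoidal part* of the
least-squares fit by $\hat\sigma$; background columns are excluded because
counting a fitted trend as "signal" inflates the ratio on trended data.
Amplitudes, being nuisance parameters, are only estimated post hoc: their
posterior means are the least-squares coefficients, recovered in the
original basis through the stored Cholesky factor.

## Model development by evidence ratios

How many Legendre orders? How many frequencies? Each choice is a model
$H$, and with equal model priors the posterior ratio of two models is
their evidence ratio. The evidence integrates the likelihood over *all*
parameters under proper, bounded priors: uniform amplitudes over
$\pm\delta_{hi}$ (default $100\times$ the data RMS, on the orthonormalised
coefficients), Jeffreys noise scale between bounds, uniform $\omega$ over
the scanned window. Bounds are shared across every model compared on one
trace, so the common normalisation constants cancel in ratios; what
survives is the Occam penalty - roughly
$\sqrt{2\pi\hat\sigma^2}/(2\delta_{hi})$ per extra model function and the
reciprocal prior width per extra frequency. Absolute ratio magnitudes
therefore depend on the chosen bounds; the *decision* (which side of 1)
is what the greedy ladders consume, and the greedy result is labelled
`status = "local"` because stopping at the first ratio above 1 does not
guarantee a global optimum over all models.

For a unimodal posterior the evidence is computed by Laplace expansion at
the mode: the finite-difference Hessian of the log posterior is
orthogonalised by eigendecomposition, all curvature directions must be
negative, and a $\log r!$ term accounts for frequency-label exchange. When
the posterior is multimodal - two tones under a one-frequency model, or a
badly underspecified background - the expansion is refused and nested
sampling takes over. Both routes share the same integrand, so their
agreement (within one nat on unimodal fixtures, tested) checks only the
$\omega$ integral, which is the point.

One caveat found while testing: on *uniformly* sampled data the posterior
repeats at alias frequencies, so a frequency prior window that extends
beyond the Nyquist limit $\pi/\Delta t$ contains exact copies of the peak
and the "widening the window costs $\log k$" rule holds only sub-Nyquist.
Non-uniform sampling removes the aliases - one more argument for it.

## Nested sampling

The sampler is a classic single-walker implementation: `n_live` points
(default 400) drawn from the uniform box prior, the worst replaced each
iteration by a constrained draw - rejection from the box while that
accepts, then a likelihood-constrained Gaussian random walk started from a
random live point with step size adapted to the live-set spread - with
trapezoidal shrinkage weights $X_i = e^{-i/n_{\mathrm{live}}}$ and
termination when the live set holds less than `termination_frac`
(default $10^{-3}$) of the accumulated evidence. The reported error is
$\sqrt{H/n_{\mathrm{live}}}$ from the information $H$. Runs are
bit-reproducible given the seed, and a likelihood plateau (the capped
perfect-fit value on noiseless fixtures) terminates the loop rather than
stalling it. Amplitudes and noise stay analytically marginalised, so the
sampled dimension is just the number of frequencies; only low dimensions
($r \le 3$ in practice) are intended, and no multi-ellipsoid or dynamic
variants are attempted. For two-frequency posteriors the label-exchange
symmetry is handled by sorting each sample; summaries are over the ordered
tuple.

## BSAL: tracking time-varying frequencies

`bsal()` runs the full single-window pipeline on a sliding window (defined
in points, so non-uniform grids work), re-fitting the background per
window but inheriting a single globally selected background order - per-window
re-selection would be slow and unstable on 10-20 point windows. Because
the posterior stays sharp even when the window covers only a third of an
oscillation period, frequency switches are localised to within about one
window of the change point. Degenerate (constant) windows are flagged, not
fatal. The default step of one point gives the dense maps the figures of
record suggest; each row of the returned density matrix is a proper
density over the shared scan grid.

## Comparators

The classical baselines live behind the same data container: the
periodogram $|FFT|^2/N$ of mean-removed data at the positive Fourier
frequencies (uniform sampling enforced - that restriction is part of the
comparison), its power-weighted mean and standard deviation
$\sigma_{FFT}$, centred moving-average detrending with shrinking edge
windows, a Hann-tapered STFT via `signal::specgram`, and
prominence-based interspike intervals (default prominence
$0.5(\max - \mathrm{median})$; the spike detector is our choice, none
being prescribed). Reading $\sigma_{FFT}$ as a power-weighted moment is an
interpretation; it reproduces the qualitative growth of spectral spread
with noise, and on the 3-second-sampled fixtures used here `sigma_BSA`
sits two orders of magnitude below it. The absolute $\sigma_{FFT}$ scale
depends strongly on the sampling interval through the Nyquist range, and
the reference values for these fixtures are only consistent with a shorter
interval than their stated sampling; since no interval is printed alongside
them, the fixtures keep the documented 3 s and the tests assert the
contrasts rather than the absolute spread.

## The simulator and what it does not emulate

`simulate_timeseries()` regenerates every validation fixture:
unit-amplitude tones (noise percentages are percentages of that unit
amplitude, so 10% means sd 0.1), additive Gaussian noise, per-sample
Gaussian phase jitter with sd $(e_p/100)\cdot 2\pi$ drawn independently
per tone (no definition being stated anywhere, this interpretation is
validated directionally: 10% jitter lowers the measured snr, as expected),
polynomial trends, harmonic stacks, piecewise frequency switches and
linear chirps. Where the record leaves parameters open the catalogue fixes
them once: the trended fixtures use 200 points at 1 s with coefficients
$-0.05t$, $-0.005t^2$, $-0.0005t^3$ (matching the documented quadratic
fixture's scale, so trend and tone stay comparable over the window); the
close-pair fixture runs 600 points at 1 s, long enough for the two-tone
posterior to separate 0.007 rad/s while the single periodogram bin
($2\pi/600 \approx 0.0105$) cannot; the plain-tone fixtures use 100 points
at 3 s. Simulated draws are seeded, platform-pinned (Mersenne-Twister,
inversion) and leave the caller's RNG stream untouched.

What passing these tests does *not* show: real traces have non-Gaussian,
heteroscedastic noise, non-harmonic spike shapes, slow amplitude drift and
chaotic period fluctuation. The harmonic fixtures probe the estimator's
statistical behaviour, not those violations; the interspike-interval tool
exists precisely because multiple ISI modes need not correspond to
multiple spectral frequencies.

## Problem sizes and defaults

Replicate medians in the acceptance script use 20 seeded realisations per
fixture; the calibration test uses 100. Nested-sampling evidence runs use
250-300 live points (120 inside the background ladder of the trended
fixture, where decisions are separated by hundreds of nats and sampler
error of ~0.3 nats is irrelevant). Coarse scans use 300 grid points over
$(0.05, 1.5]$; fine sampling uses 201 points (61 per axis in two
dimensions). These sizes keep a full analysis of one 100-600 point trace
in the 0.1-10 second range on one core while leaving every decision margin
far above sampler noise.

## Known limitations

Laplace evidences for $r \ge 2$ require a caller-supplied starting tuple
and are rarely preferable to nested sampling, which the selection ladder
uses for all multi-frequency models. The greedy ladders are model
*development*, not exhaustive model selection. Absolute evidence values
(not ratios under shared priors) are prior-bound-dependent by construction.
Aliases on uniformly sampled data are not deduplicated - the scan window
should stay below Nyquist, or the sampling should be non-uniform. The STFT
and periodogram require uniform sampling by design; that is the contrast
being drawn, not an oversight.
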