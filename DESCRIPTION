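Package: bsafreq
Title: Bayesian Spectrum Analysis for Biological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency detection in short, noisy, trended and possibly
    non-uniformly sampled biological time series by Bayesian Spectrum
    Analysis (BSA). Amplitudes and noise are marginalised analytically so
    the posterior concerns angular frequency alone; polynomial background
    trends are modelled with Legendre bases and their expansion order is
    chosen automatically by evidence ratios, as is the number of
    frequencies. Evidence is computed by Laplace approximation on unimodal
    posteriors and by Nested Sampling otherwise. A windowed local variant
    (BSAL) tracks time-varying frequencies. Classical comparators
    (periodogram, STFT, moving-average detrending, interspike intervals)
    and a seeded simulator of harmonic test signals are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
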