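---
title: "Criticality-sensitive EEG biomarkers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criticality-sensitive EEG biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critEEG)
```

## The science in brief

Neuronal networks are hypothesized to operate near a critical point between
ordered and disordered dynamics, with the excitation/inhibition (E/I) balance
acting as the control parameter. critEEG implements two EEG proxies of this
regime and the inferential machinery to relate them to a covariate of
interest (here: IQ) across a ranked cortical hierarchy:

* **fE/I**, the functional excitation/inhibition ratio of a narrow-band
  oscillation. The signal is band-pass filtered, its amplitude envelope
  `A(t)` extracted (analytic-signal magnitude), and the signal profile
  `S(t) = sum_{k<=t} (A(k) - <A>)` is split into overlapping windows. Each
  profile window is divided by its mean envelope amplitude and linearly
  detrended; the standard deviation of the result is the normalized
  fluctuation `nF_w`. With `r` the Pearson correlation between window
  amplitudes and `nF_w` over all windows,

  `fE/I = 1 - r`.

  A critical network shows no residual amplitude-fluctuation covariance
  (`fE/I = 1`); inhibition dominance gives `fE/I < 1`, excitation dominance
  `fE/I > 1`. Because the biomarker reads a covariance that only exists in
  the presence of long-range temporal correlations (LRTC), it is gated on
  the DFA exponent of the same envelope: results with DFA <= 0.6 are
  reported missing rather than interpreted.

* **DFA**, detrended fluctuation analysis of the amplitude envelope
  (classical DFA-1): RMS of linearly detrended profile windows, averaged per
  log-spaced window size; the scaling exponent is the log-log slope. 0.5
  means no memory, values toward 1 strong LRTC.

* **The aperiodic 1/f exponent** `beta` of the power spectrum
  (`power ~ f^-beta`), fitted over 1-5 Hz — below the alpha peak, where
  spectral scaling is most informative about E/I balance — by a spectral
  parameterization that decomposes the log-spectrum into an aperiodic
  component plus up to 6 Gaussian peaks (widths 2-12 Hz, minimum modeled
  height 0.1 log10 units). The same engine fitted over 1-40 Hz yields the
  peak alpha frequency (PAF: the largest modeled peak in 6-14 Hz) and its
  height above the aperiodic fit; the individualized alpha band is
  PAF +/- 2 Hz, split into two half-bands for fE/I.

Biomarkers are averaged into seven functional networks per hemisphere,
ranked 1-7 along the sensorimotor-association hierarchy (visual = 1,
somatomotor = 2, dorsal attention = 3, salience = 4, limbic = 5,
control = 6, default = 7; sensorimotor = ranks 1-3, association = 4-7 —
a declared, editable convention), and modeled at two spatial scales.

## Statistical models

Per biomarker the package fits, in increasing structure:

1. **Region OLS** — per-subject region mean on IQ + age + sex; the
   standardized IQ slope is reported.
2. **Multilevel models** — long-format region records (2 regions x 2
   hemispheres x optional 2 bands per subject) with fixed age, sex,
   hemisphere (band), a hierarchy x IQ interaction and random subject
   intercepts; denominator df by the Satterthwaite approximation
   (lmerTest), with a labeled normal-approximation fallback. Interactions
   are probed with Johnson-Neyman intervals: the simple slope of the focal
   term across the IQ grid with its delta-method SE, and the moderator
   range where it is significant; an oracle test checks the interval
   against brute-force recentering.
3. **GAMMs** — mgcv::gam with linear covariates, linear interaction terms,
   a tensor-product interaction smooth (`ti`, so the smooth is identifiable
   next to its own linear part), and `s(subject, bs = "re")` random
   intercepts; `select = TRUE` with REML enables shrinkage of uninformative
   smooths to (near) zero effective df. Prediction surfaces are exported at
   IQ = mean and mean +/- 1 SD.

Bonferroni correction uses `m` = number of non-intercept fixed effects plus
non-subject smooths, computed from the fitted model and reported alongside
(`m_effects`), since the family size is model-dependent.

Wilcoxon rank-sum contrasts between age groups use midranks for ties;
the high/low-IQ subgroup contrast is a Welch t test between subjects at
least 1 SD above versus below the sample IQ mean.

## What the synthetic generator emulates

`generate_signal()` builds one channel as

```
x(t) = env(t) * sin(2*pi*f_alpha*t + phi) / sd + background(beta) / osc_snr
```

with `env = exp(0.15 * z)`, `z` fractional Gaussian noise of Hurst exponent
`hurst` (exact circulant-embedding synthesis) low-passed at 3 Hz, and
`background` Gaussian noise with PSD ~ `f^-beta` by spectral shaping. Design
rationale, fixed once:

* **Multiplicative (log-normal) envelope.** The fE/I normalization divides
  window fluctuations by window amplitude; only fluctuations proportional
  to the local level cancel exactly, which is what a multiplicative
  envelope provides. An additive envelope (`1 + c*z`) would make `nF`
  scale as `1/amplitude` and bias fE/I above 1 even without coupling.
* **3 Hz modulation cutoff.** Keeps the oscillation strictly inside
  `f_alpha +/- 3` Hz, so it cannot leak into the 1-5 Hz aperiodic fit
  range, while leaving all DFA scales (>= 2 s, i.e. < 0.5 Hz) untouched.
* **Modulation depth 0.15.** The fE/I window amplitude is an arithmetic
  window mean; under a log-normal envelope its Jensen term correlates with
  within-window fluctuation energy and biases fE/I below 1, roughly
  linearly in the depth. Depth 0.15 keeps that structural bias within the
  Monte-Carlo tolerance of the zero-coupling contract (fE/I = 1, checked
  by the test suite) while keeping the modulation visible; it is shallower
  than typical empirical alpha modulation, a deliberate trade-off.
* **Coupling kappa.** Within each 5-s block, detrended envelope
  fluctuations are multiplied by `1 + kappa * z_w` (`z_w` the standardized
  block mean amplitude, gain floored at 0.05), so
  `sign(corr(amplitude, nF)) = sign(kappa)` and `sign(1 - fE/I) =
  sign(kappa)`, without changing mean power. This manipulates exactly the
  covariance fE/I measures.

`generate_cohort()` draws age ~ uniform(6, 19), sex ~ Bernoulli(0.5), IQ ~
normal(111, 13) truncated to [71, 145] (rejection sampling), and biomarker
records `b0 + eff*(IQ - 111)*(rank - 4) + u_subject + e` — a pure
rank-by-IQ interaction of known size for parameter-recovery and
type-I-error studies. Defaults (n = 128; 194-s, 250-Hz recordings) mirror
the cohort the package targets. The simulated-recording path of
`run_pipeline()` additionally varies the per-subject peak alpha frequency
uniformly over 9.5-11.5 Hz so individualized-band analyses have realistic
between-subject spread, and maps the injected interaction onto per-channel
coupling.

**What the generator does not emulate:** artifacts (blinks, muscle, line
noise), non-stationary state changes, spatial correlation between channels,
volume conduction, or any biophysical network dynamics. Passing tests
therefore demonstrate correctness of the estimators and models under a
clean generative model, not robustness to real-world EEG contamination —
preprocessing is explicitly out of scope.

## Numerical choices

* Band-pass: Hamming-window FIR (signal::fir1), ~1 Hz transition, odd
  length `round(3.3 * fs)`, applied by FFT convolution with group-delay
  compensation (zero-phase); one filter half-length is trimmed from each
  envelope edge. -6 dB points sit at the band edges, so the band-power
  fraction of broadband noise is conserved.
* Envelope: FFT half-spectrum analytic signal magnitude.
* DFA: log-spaced sizes (default 10 in 2-20 s), 50% window overlap,
  linear detrending, mean of per-window RMS; amplitude-scale invariant.
  The 2-s lower bound sits well above two periods of the lowest alpha
  band edge; note that envelopes of *band-passed noise* still carry
  filter-induced short-range correlations whose DFA crossover reaches
  beyond 2-s windows, which is why random-envelope calibration (0.5) is
  stated for uncorrelated envelopes and band-passed white noise reads
  ~0.55-0.6 — below the 0.6 gate either way.
* fE/I: 5-s windows, 80% overlap by default (3-6 s / 75-85% supported for
  sensitivity sweeps); minimum 10 usable windows; zero-amplitude windows
  dropped pairwise; the gate is applied per channel x band on the
  full-signal DFA exponent, before network averaging.
* Welch PSD: 4-s Hann segments, 50% overlap, mean averaging; 0.25 Hz
  resolution gives >= 16 bins across the 1-5 Hz fit.
* Spectral parameterization: robust aperiodic fit (refit on points at or
  below the initial line), iterative peak extraction on the flattened
  spectrum, joint L-BFGS-B refinement, aperiodic refit on the
  peak-removed spectrum; fixed (no-knee) aperiodic mode only.
* Imputation: chained regression forests (ranger) over age, sex, IQ,
  rank, hemisphere, band and a leave-one-out subject sibling mean,
  iterated while the out-of-bag RMSE improves; seeded, flags preserved;
  degenerate designs fall back to labeled cell-mean fill.

## Problem sizes used in tests

The test-suite replications are sized for a desk run: biomarker
calibrations use 20 seeds of 194-300 s signals; type-I-error calibration
uses 500 null cohorts of 32 subjects; parameter recovery uses 50 cohorts of
128 subjects; pipeline tests use 2-6 simulated subjects at 60-120 s. The
full-scale demo (32 subjects, 14 mapped channels, 180 s) runs from the CLI
in a few minutes.

## Known limitations

* The sensor-space network map is a declared convention, not a source
  model; hierarchy conclusions transfer to real data only insofar as the
  map does. A user-supplied map (e.g. a 68-parcel atlas) is accepted
  wherever the default is.
* The DFA fit range and window-size count are package defaults, stated
  rather than inherited from any particular reference analysis;
  both are configurable.
* The spectral fitter is self-contained; it follows the same decomposition
  logic as the specparam family but is not a line-for-line port, and only
  supports the fixed aperiodic mode.
* fE/I gating means missingness is informative (near-random envelopes are
  excluded by construction); the imputer conditions only on observed
  covariates and sibling values.
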