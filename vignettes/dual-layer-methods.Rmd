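---
title: "Dual-layer EEG artifact removal and gait-cycle spectral analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-layer EEG artifact removal and gait-cycle spectral analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duallayer)
```

## The problem

Scalp EEG recorded during walking is contaminated by three artifact classes
that overlap the cortical signal in both time and frequency: mechanical
motion artifacts locked to heel strikes (dominant below ~15 Hz, with
broadband onsets), electromyographic activity from neck muscles (broadband,
20 Hz and up), and environmental electrical noise (line frequency and
harmonics). Dual-layer electrode arrays address this at the hardware level:
each scalp electrode is paired with a mechanically coupled but electrically
isolated noise-only electrode referenced to an artificial-skin circuit, so
the outer layer records the motion and electrical artifacts without any
brain contribution. This package implements the signal-processing side of
that design: noise-referenced cleaning of the scalp channels, stacked-channel
ICA with spectral component-rejection rules, and gait-cycle time-frequency
analysis with bootstrap statistics.

Six processing variants are orchestrated by `run_pipeline()`:

1. `single` — channel conditioning only (1 Hz zero-phase high-pass, robust
   kurtosis/SD channel rejection, common average reference, downsampling);
2. `asr` — plus artifact subspace reconstruction calibrated on a standing
   baseline (`asr_calibrate()`, `asr_clean()`);
3. `dual` — stacked-channel ICA without additional cleaning;
4. `noise_cancel` — frequency-domain noise cancellation against
   spline-interpolated virtual noise channels (`cancel_recording()`);
5. `dual_asr` — ASR followed by stacked ICA;
6. `pca_cca` — windowed PCA cleaning then windowed lag-1 CCA cleaning, both
   with noise-referenced criteria, followed by stacked ICA.

## Frequency-domain noise cancellation

`cancel_channel()` transforms the scalp channel and its matched noise
channel with the same sliding-window FFT (0.5 s Hann windows, 94% overlap,
so the hop is 8 samples at 256 Hz). Two median-relative criteria flag bins
for cancellation:

* **transient pass** — bins whose noise magnitude exceeds 6x that window's
  median noise magnitude; this catches heel-strike motion transients;
* **persistent pass** — bins whose noise magnitude exceeds 2x the median in
  at least 90% of windows; this catches stationary electrical noise such as
  the line frequency. A bare "below 2x median" reading would flag most of
  the spectrum, so the lower cutoff is interpreted as a persistence
  criterion; both multipliers are configurable
  (`cancellation_config()`).

At flagged bins the noise coefficient, rescaled so the window's median noise
magnitude matches the window's median EEG magnitude, is subtracted
complex-valued; because the two layers are mechanically coupled, artifact
content is phase-aligned across layers and cancels, while unrelated content
at the same bin is partially retained. The result is floored so a bin's
magnitude can never grow (a bin dominated by the scaled noise coefficient
is cancelled to zero), and `cancel_mode = "zero"` switches to plain bin
zeroing. Every criterion is a ratio of magnitudes, which makes the whole
operation exactly scale-equivariant and an exact identity when the noise
channel is silent.

The inverse transform is a weighted overlap-add with per-sample
window-power compensation. The analysis pads both ends of the signal by one
full window so that every real sample sits under the complete window stack;
without this, samples near the edges have near-zero analysis weight and any
modification of the spectra would be amplified there by the normalization.
With unmodified coefficients the round trip is exact to floating-point
precision over the entire signal.

Since only 40 noise electrodes cover 128 scalp positions,
`interpolate_noise_layer()` builds a virtual matched-noise channel at every
scalp position by spherical-spline interpolation (stiffness order m = 4,
ridge 1e-5, 50-term Legendre series — fixed, logged hyperparameters; the
constraint term reproduces constant fields exactly).

## Windowed subspace cleaning

`pca_window_clean()` slides 0.5 s windows with 50% overlap. In each window
the scalp channels are decomposed by PCA; score samples deviating more than
2 SD from the component's median are replaced by the median (the literal
"SD from the median" rule; a MAD-scaled variant is available), and
components whose absolute correlation with the noise-layer mean trace is
more than 5 SD above the median of all component–noise correlations are
additionally cleaned by frequency-domain cancellation with a 2x flag
multiplier. Windows are re-assembled with a raised-cosine cross-fade, which
is exactly identity-preserving where nothing was modified and avoids
boundary discontinuities that would themselves look like artifacts.

`cca_window_clean()` slides 3 s windows with 50% overlap and solves the
canonical correlation between the data and its one-sample lag by whitening
both views and taking the SVD of the cross-covariance (ridge-regularized
only when a covariance is near-singular, so full-rank solutions agree with
the textbook generalized eigenproblem to machine precision). The canonical
correlations are the components' lag-1 autocorrelations, so components
order from smooth (motion-like) to rough (muscle/electrical-like). Flagged
for cleaning are: components after the knee of the autocorrelation profile
(knee = maximum perpendicular distance to the first-to-last chord, ties
resolved toward the larger index so flat or linear profiles flag nothing),
components with negative spectral skewness (power concentrated at high
frequency), and components whose spectral skewness or kurtosis lies more
than 2 SD from the median across components. The spectral moments are
computed on heavily averaged short Welch segments (0.5 s, 50% overlap):
the moments need stable estimates far more than fine frequency resolution,
and noisy estimates would turn the outlier rule into a random sampler of
components.

The simplified ASR comparator (`asr_calibrate()`, `asr_clean()`) uses a
fixed PCA basis from the standing baseline with per-component RMS
thresholds at mean + k·SD (k = 7 by default) over 0.5 s windows; in the
uncorrelated calibration basis, reconstruction from the sub-threshold
subspace reduces to removing the exceeding components' content in that
window. The full Riemannian/geometric extensions of modern ASR builds are
deliberately out of scope — the comparison needs the method's behaviour,
not a specific toolbox build.

## Stacked ICA and component rejection

For the dual-layer variants the cleaned scalp channels are stacked with the
amplitude-matched noise channels (`amplitude_matched_noise()`: each noise
channel rescaled per window so its median Fourier magnitude matches its
paired scalp channel's, compensating the impedance difference of the
artificial-skin circuit) and the EMG channels, concatenated across speed
conditions, PCA-reduced (to scalp + EMG dimensionality by default,
mirroring the 176-to-136 reduction of the full montage), and unmixed with
FastICA (symmetric orthogonalization, tanh contrast). FastICA was chosen as
the implemented algorithm because it is deterministic given the seed,
converges robustly, and the tanh contrast handles both sub- and
super-Gaussian sources; the decomposition is sign-fixed and
variance-ordered so repeated runs are bit-identical.

`reject_components()` applies two spectral rules on Welch spectra over
2–100 Hz (1 s Hann segments, 50% overlap): a component is rejected when the
OLS slope of its dB spectrum against linear frequency is at or above
−0.06 dB/Hz (spectrally flat, sensor-noise-like), or when the R² of a
2nd-order polynomial regression of its spectrum on any noise-layer or EMG
reference spectrum reaches 0.99 (artifact-matching; the maximum over
per-channel references is used rather than an averaged reference). Both
thresholds are inclusive and configurable; rejection is monotone in both.

## Gait-cycle ERSP and statistics

Gait events come either from a supplied event table or from vertical
ground-reaction forces (`detect_gait_events()`: 20 N threshold crossings
with 100 ms debounce). Epochs span right heel strike to right heel strike;
strides whose within-cycle events violate the order rhs < lto < lhs < rto
are flagged invalid and excluded. Epochs are carried with a 0.3 s context
margin so the Morlet estimates at the stride boundaries rest on real
neighbouring data — without context, the wavelet power rolls off at the
epoch edges and masquerades as cycle-locked modulation at 0%/100%.

`single_trial_tfr()` uses complex Morlet wavelets with cycle counts scaling
linearly from 3 at the lowest analysis frequency to 8 at the highest.
`time_warp()` maps each epoch's event latencies onto the across-epoch
median latencies piecewise-linearly and resamples onto a fixed 200-point
0–100% grid (0% and 100% are both right heel strike).

`ersp()` uses the full-cycle mean log power within the condition as the
baseline — gait has no quiet pre-stimulus window, so the full-cycle mean is
the standard reference. Significance comes from a surrogate distribution:
each of 200 bootstrap iterations draws one random time column per epoch and
averages across epochs; deviations of these surrogates from the baseline
form the per-frequency null, and cells are kept when their empirical
two-tailed p-value (with the +1 correction) is at most alpha. On
exchangeable input this mask has empirical size alpha by construction.

`speed_comparison()` computes a per-frequency one-way F statistic across
conditions of per-epoch mean log power and builds the null by permuting
condition labels across epochs (1000 permutations by default) — the
exchangeable-null reading of a non-parametric ANOVA. The same ERSP and
comparison machinery applied to raw noise-layer or EMG channels
(`channel_level_analysis()`) provides the artifact-reference view.

## The synthetic generator

`generate_dataset()` emulates the study conditions: four treadmill speeds
(0.5, 1.0, 1.5, 2.0 m/s) of 3-minute walking (tests and the acceptance
script use 30–60 s), a standing baseline, and a 128/40/8
scalp/noise/EMG montage at 512 Hz (reduced geometries are used throughout
the tests). Design choices, each fixed once:

* **Stride timing** — stride period log-linear in speed between 1.6 s at
  0.5 m/s and 1.0 s at 2.0 m/s (≈1.26 s at 1.0 m/s), with 3% Gaussian
  stride-to-stride jitter; left toe off, left heel strike, and right toe
  off at 12%, 50%, and 62% of each stride.
* **Brain** — two lateralized sensorimotor sources over C3/C4-like
  positions (pink background plus 10 Hz alpha and 20 Hz beta whose
  envelopes are cosine-locked to the gait phase: the left source peaks at
  left heel strike and bottoms during right-limb swing, mirrored on the
  right), riding on a distributed 1/f background. The background is
  volume-conducted (many cortical patches with smooth topographies), each
  patch carrying its own rhythm (6–25 Hz) with varying 1/f exponent and a
  seconds-scale waxing-waning envelope. These features are what real EEG
  backgrounds have, and they matter: spatially independent or spectrally
  identical backgrounds would make outlier-based component criteria behave
  pathologically, and Gaussian stationary sources would be unseparable by
  ICA in principle. A per-speed gain (1.0 at 0.5 m/s to 0.7 at 2.0 m/s)
  programs the alpha/beta speed effect.
* **Motion** — damped 2–12 Hz bursts (~0.2 s) time-locked to both heel
  strikes, confined to roughly the double-support interval; amplitude grows
  with speed (0.6x at 0.5 m/s to 1.8x at 2.0 m/s). Many latent burst
  fields with smooth loadings give each electrode a distinct artifact
  mixture — electrode-level rattling, not one rigid cap mode, which is the
  premise of pairing every electrode with its own noise sensor. Each scalp
  channel's artifact equals the latent field at its position times a
  per-channel coupling gain (0.5–2.0) plus 5% decorrelation noise; the
  noise layer records the same field at the paired positions.
* **EMG** — four neck-muscle sources (left/right sternocleidomastoid and
  trapezius), 20–124 Hz band-limited noise with envelopes peaking in double
  support with the contralateral limb leading; full projection onto the
  8 EMG channels and spatially decaying leakage onto the scalp.
* **Line and sensor noise** — a common 60 Hz sinusoid with per-channel
  gains, and 1 µV RMS white sensor noise.
* **Forces** — stylized double-bump vertical GRF per stance with a sharp
  (30 N) onset so threshold-based event detection recovers the programmed
  events to the sample.

The emitted scalp EEG equals the sample-wise sum of the returned
ground-truth parts, and a fixed seed reproduces a dataset bit-exactly, so
every cleaning stage can be scored against known truth. What the generator
does **not** emulate: ocular artifacts, electrode drift and pops,
biomechanically realistic forces, or a conductive head model beyond smooth
topographies — passing tests show the pipeline recovers the programmed
structure under these idealized artifact classes, not that it handles every
failure mode of real mobile recordings.

## Numerical choices and degenerate inputs

Zero-noise windows (median magnitude 0) flag nothing — there is nothing to
cancel and no ratio to form. Rank-deficient PCA windows pass through
unchanged. Near-singular CCA covariances receive a ridge of
1e-6 · trace/n. An empty kept-component set falls back to keeping
everything rather than returning silence. Event indices are 1-based
throughout, and BDF/EDF round trips are exact to one least-significant bit
of the 24-/16-bit integer encoding.

## Problem sizes

The test-suite and acceptance-script experiments run at a reduced desk
scale chosen as the package's own evaluation design: 16–32 scalp channels,
6–10 noise channels, 256 Hz, 20–60 s per condition, 10 seeds for the
recovery comparison, 50–60 seeds for the calibration checks. The full
128/40/8 geometry at 512 Hz runs through exactly the same code paths.

## Known limitations

The PCA score-replacement rule (2 SD from the median) modifies ~5% of
samples even on clean Gaussian data; this is the method as defined — its
aggressiveness is a property the original design accepted, and it is why
the cleaned-output comparisons in the tests measure recovery against ground
truth rather than assuming cleaning is harmless. AMICA and dipole-level
analyses (source localization, residual-variance filtering, cross-subject
clustering) are outside the package's scope; component rejection operates
purely on spectra.
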