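---
title: "Detecting hypovolemia from PPG heart-rate-band amplitude trends: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hypovolemia from PPG heart-rate-band amplitude trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgtrend)
```

## The problem and the signal model

Progressive blood loss reduces stroke volume before it moves the classic
vital signs; one of its earliest non-invasive correlates is a decline in the
pulsatile amplitude of the photoplethysmogram. `ppgtrend` operationalizes
this as a trend statistic: track the amplitude of the PPG's time-frequency
spectrum inside the heart-rate band (AM_HR) across a recording, fit a line,
and classify the recording from four summary features — the line's r², its
slope, and the percentage and signed change between the first and last AM_HR
values. Positive trends are read as euvolemia, negative ones as blood loss.

The method assumes the recording is long enough to show a trend (at least
two 2-minute sequences, i.e. 240 s), that one of the available channels is
of usable quality, and that heart-rate energy stays inside the analysis band
(0.66–3 Hz by default, 40–180 bpm). It does not assume a baseline
measurement before blood loss began — only relative change within the
recording matters.

## Channel selection by histogram entropy

Each sensor records several PPG channels; one is selected per recording by
minimum Shannon entropy of the amplitude histogram (50 bins over a
normalized range). A clean PPG pulse spends most of its time near the
diastolic baseline with brief systolic excursions, so its histogram is
concentrated (low entropy); noise and contact artifacts spread occupancy
across bins.

The normalization range is a deliberate design choice. Under plain min–max
normalization, a handful of extreme samples — exactly what additive noise
produces — stretch the range, squeeze the bulk of the histogram into fewer
bins, and can *lower* a noisier channel's entropy. We therefore normalize
over the 1st–99th percentile range and clamp outliers into the end bins.
This keeps the estimator invariant to affine rescaling while making mean
entropy increase monotonically with additive noise SD on synthetic records
(a property the test suite checks over 20 seeds). Plain min–max remains
available via `clip_quantiles = c(0, 1)`. Ties in the arg-min go to the
lowest channel index. Entropy is computed over the whole recording, since
one channel is chosen per recording.

## VFCDM time-frequency estimation

The spectral engine is two-stage complex demodulation at an analysis rate
of `fs_d = 20` Hz (decimated from 80 Hz by a zero-phase anti-alias FIR at
`0.45 * fs_d`):

* **Stage 1 (fixed CDM).** For centers `f_c = Fw, 2Fw, …, f_max − Fw`
  (`Fw = 0.5` Hz, `f_max = 10` Hz), multiply by `exp(−i 2π f_c t)` and
  low-pass at `Fw`. Each band yields an instantaneous amplitude `2|z|`,
  phase, and frequency `f_c + φ'/2π` (central differences of the unwrapped
  phase, one-sided at the ends).
* **Stage 2 (variable-frequency refinement).** Re-demodulate the original
  signal along each band's instantaneous-frequency trajectory (cumulative
  trapezoidal phase integral) and low-pass at the narrower `Fv = 0.15` Hz.
  Because the demodulation now sits on the signal's own frequency, the
  refined amplitude is insensitive to where the tone fell within the stage-1
  band — this is what makes the spectrum "high-resolution" and the amplitude
  calibration flat across the band, including tones exactly midway between
  centers.

Refined amplitudes are deposited at the nearest bin (grid spacing 0.1 Hz) of
their refined instantaneous frequency, keeping the maximum on collision —
appropriate because the downstream statistic is a band maximum.

Numerical choices worth recording:

* Both FIR stages share one length (`4 fs_d / Fw` rounded odd, 161 taps =
  8 s), Hamming-window design normalized to unit DC gain; filtering is done
  by FFT convolution with reflect-padding and exact group-delay
  compensation, so the filters are exactly zero-phase.
* A band's instantaneous frequency is clamped to `f_c ± Fw`. Outside that
  window the phase derivative of a nearly-empty band is leakage-driven
  noise; without the clamp such bands chase remote components in stage 2 and
  deposit spurious ridge amplitude. The clamp is also the band's contract:
  stage-1 content farther than `Fw` from the center is stopband.
* The first and last `filter_len − 1` samples (8 s at the defaults) of each
  window are inside the cascaded filters' transients; every spectrum carries
  this as `edge_s`, and all downstream statistics exclude the edge region.
* Amplitude calibration, instantaneous-frequency accuracy, chirp tracking,
  stage-1 linearity and approximate reconstruction are all validated against
  FFT/analytic-signal oracles in the test suite; the defaults are design
  choices validated by those properties, not values with intrinsic meaning.
  Adjacent stage-1 bands overlap (spacing `Fw`, cutoff `Fw`), so the
  reconstruction identity carries a factor 1/2.

## From spectra to features

Sequences default to consecutive non-overlapping 120-s blocks (start times
are user-specifiable for irregular clinical recordings); each block is
decimated once and holds seven 60-s windows shifted by 10 s. Per window, the
heart-rate-band maximum of the spectrum is averaged over interior time
samples; the seven window values average to the sequence's mean AM_HR. We
average all seven windows rather than using only the last one — the windows
are overlapping views of the same block, and averaging reduces estimator
variance without changing the trend.

The trend line is ordinary least squares of AM_HR against sequence-center
time. Conventions for degenerate inputs: a constant series has `SS_tot = 0`
and is assigned r² = 0 (a flat series carries no trend evidence; slope and
both changes are 0), and a first AM_HR value of exactly 0 makes the
percentage change undefined and raises an error rather than yielding NaN.
The signed change is kept signed — the sign *is* the classifier's
physiological rationale. Truncating a record to its leading portion (for
early-detection analyses at moderate blood loss) is supported down to the
240-s minimum.

## The evaluation protocol

Class balancing (undersampling the majority class to the minority size),
10 balanced resamples × 10 row permutations, stratified 4-fold
cross-validation, and an exhaustive γ × C grid (7 × 58 cells; C spans 0.01
to 5·10¹⁸) reproduce a deliberately conservative evaluation design: every
averaged cell metric rests on 100 independent runs. Decisions the protocol
leaves open, and our choices:

* **Stratified folds.** Stratification preserves the deliberately balanced
  classes inside every fold; a fold that lost a class entirely would make
  sensitivity/specificity undefined. (Plain k-fold is what stratification
  degenerates to when classes are exchangeable, so nothing is lost.)
* **No feature scaling by default.** The features live on their natural
  scales (the percentage change dominates distances); `standardize`
  (training-fold statistics only, applied to the held-out fold) is available.
* **Tie-breaking** for the optimal cell: smaller C, then smaller γ — the
  less flexible model wins ties.
* **Seeds.** Resample `r` uses `seed + 1000 r`; run `(r, p)` permutes rows
  with `seed + 1000 r + p`; fold assignment is a deterministic per-class
  round-robin over the permuted order. The whole experiment is a pure
  function of (feature table, seed, config, grid), which the tests verify.
* BL is the positive class everywhere: sensitivity is the blood-loss
  detection rate. With balanced classes, overall accuracy equals the mean of
  sensitivity and specificity, which the tests check as an invariant.

SVM training itself is delegated to `e1071` (libsvm); the package pins the
contract — Gaussian kernel, cost C, binary labels, no internal scaling —
not the solver.

## The synthetic cohort: what it does and does not emulate

`simulate_record()` builds each channel as

```
a(t) · (1 + m sin 2π f_r t) · Σ_k sin(2π (k+1) f_h t − kπ/2) / (k+1)
    + m A₀ sin 2π f_r t + wander + noise
```

with a linearly decaying envelope `a(t)` (from `A₀` to
`A₀ (1 − amp_decay_frac)`), respiratory amplitude modulation plus an
additive sub-0.5-Hz respiratory component, sinusoidal baseline wander, and
per-channel white Gaussian noise. The harmonic phases `−kπ/2` align all
harmonic maxima, giving the sharp systolic peak of a real pulse — this
matters: a phase-scrambled (sawtooth-like) carrier has a spread amplitude
histogram and breaks the premise that lower entropy means a cleaner channel.
Linear (not exponential) envelope decay matches the linear trend-line model
applied downstream.

The default cohort preset mirrors a realistic clinical imbalance — 29 BL and
65 NBL recordings — with per-record heart rates drawn from 0.9–1.8 Hz,
respiratory rates from 0.15–0.4 Hz, BL envelope decay from 30–60%, NBL
drift from ±5%, three channels with noise SDs (0.05, 0.15, 0.30) of the
unit pulse amplitude, and 600-s records (five AM_HR points each; long
enough for a stable trend, short enough that the full test suite and the
acceptance script run in minutes on one CPU). Record `i` uses seed
`master + i`, so cohorts are portable across platforms. No quantitative
effect size for the AM_HR decline at a given withdrawn volume is available
to calibrate against, so the class separation is a free parameter of the
generator, chosen once as above.

What the generator does **not** emulate: motion artifacts and contact loss
(the dominant real-world failure mode; signal-quality screening beyond
entropy selection is out of scope), beat-to-beat morphology and heart-rate
variability, vasoconstriction dynamics, sensor-specific transfer functions,
and SpO₂. Consequently, passing tests demonstrate that the pipeline recovers
the trends it assumes from signals with the assumed structure — parameter
recovery, not clinical validity. Classification accuracy on the synthetic
cohort saturates near 100% because the classes are separable by
construction; it bounds nothing about clinical performance, where reported
accuracies for this family of methods are far lower.

## Known limitations

* Channel selection is global per recording; a channel that degrades halfway
  through is still used whole.
* The AM_HR aggregation (band maximum → time mean → window mean) is one
  reading of "mean amplitude in the heart-rate band"; a median variant would
  be more outlier-robust and is a natural extension.
* Sequences are non-overlapping consecutive blocks by default, whereas
  clinical recordings may need hand-placed sequence starts around
  interruptions (supported via `window_scheme(starts = ...)`).
* The extreme upper end of the C grid (up to 5·10¹⁸) is retained for
  protocol fidelity; at those values the soft-margin penalty is effectively
  hard-margin and many cells are redundant.
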