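---
title: "Models and methods: segmenting naturalistic arm movements and modeling event-related spectral power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`naturalreach` reimplements, as a tested pipeline on synthetic data, an
analysis chain for naturalistic arm movements recorded alongside
intracranial (ECoG-style) neural data: wrist trajectories from video are
segmented into *move* and *rest* states; movement-initiation events are
detected and pruned; multichannel recordings are cleaned; event-related
Morlet spectral power is computed, baseline-normalized, projected onto
atlas regions, and masked by a baseline bootstrap null; and per-event
low-/high-frequency band power is regressed on ten behavioral and
environmental features with a robust loss, forward selection, repeated
day-balanced splits, and permutation feature importance.

Every stage is driven by a synthetic-study generator with known ground
truth, so all tests run without any external data.

# The behavioral state model

Wrist keypoint paths (30 frames/s, image pixels, y growing downward, about
3 px per cm) are modeled by a two-state first-order autoregressive hidden
semi-Markov model. The two states strictly alternate, so the chain is
described by per-state dwell laws and observation models:

* **Observations.** The model observes per-frame displacement vectors
  $z_t = p_{t+1} - p_t$ rather than raw positions, which makes the AR(1)
  observation law $z_t \mid s \sim N(A_s z_{t-1}, \Sigma_s)$ stationary
  within states. The source analysis does not state whether positions,
  displacements, or speeds are observed; displacements are the package's
  choice (documented here), and the innovation covariance trace cleanly
  separates holding still from moving.
* **Dwell law.** Negative binomial on dwell $-$ 1 (geometric as the
  `size = 1` special case), truncated at `max_dwell` frames (default 150,
  i.e. 5 s) for a tractable duration-explicit Viterbi.
* **Fitting.** Exact EM: the E-step is a segment-based forward-backward
  pass with the final dwell right-censored through the survivor function;
  the M-step refits $A_s, \Sigma_s$ by $\gamma$-weighted least squares and
  the dwell laws by weighted maximum likelihood that includes the censored
  final segment. The observed-data log-likelihood is non-decreasing at
  every iteration (asserted in tests). Initialization is 2-means on frame
  speed under a fixed seed; after convergence states are relabeled so that
  *rest* has the smaller innovation trace, which makes the output invariant
  to initialization permutations.
* **Decoding.** Duration-explicit Viterbi under the same censored-end
  convention. On all sequences of 12 frames or fewer the decoded path is
  verified against exhaustive enumeration of every alternating
  segmentation.

# Event detection and pruning

A movement-initiation event is a rest-to-move transition preceded by at
least 0.5 s of contiguous rest and followed by at least 0.5 s of contiguous
move (contiguity is assumed; the source text does not distinguish
contiguous from predominant windows). Event duration is the length of the
move dwell containing the onset. Events are pruned by: duration within the
*closed* interval [0.5, 4] s (the source writes "between 0.5-4 s" without
bounds semantics; closed is the package's documented choice); mean
keypoint confidence over the dwell strictly greater than 0.4; the
coefficient of determination of a quadratic fit of radial displacement
versus time over the dwell strictly greater than 0.6; and, per recording
day, at most the 200 events with the highest onset speeds, ties broken by
earlier onset for determinism. Onset speed is the mean radial speed over
the first 0.5 s of the dwell (the source does not fix the window).

# Neural preprocessing

Fixed order: median (DC) removal per channel; zeroing of samples whose
channel-averaged absolute voltage exceeds median + 50 IQR, padded by
&plusmn;2 s (a mask records zeroed samples); zero-phase FIR band-pass
1-200 Hz with notches at 60/120/180 Hz and decimation to 500 Hz;
common-median rereferencing within each electrode group (lower central
order statistic for even group sizes, fixed for reproducibility); and
bad-channel flags for SD > median + 5 IQR or kurtosis > median + 10 IQR
across channels. "IQR, > k" rules are read one-sided high; whether
abnormally low SD should also flag a channel is left open and the rule is
configurable. Since no signal-processing package is assumed, FIR design
(windowed sinc, Hamming), forward convolution with group-delay removal and
odd-reflection padding, and Welch PSD are implemented in the package and
tested against closed-form responses (notch attenuation, passband
flatness, window arithmetic).

# Spectral analysis

Ten-second voltage segments centered on each onset (at 500 Hz) are
discarded if their mean log spectral density over the 1-124 Hz analysis
band is below 0 dB (a missing-data proxy: zeroed stretches collapse the
PSD) or if 115-125 Hz power exceeds the across-segment mean by more than
3 SD. Morlet wavelets on a 4-124 Hz grid in 2 Hz steps (the source plots
roughly 4-120 Hz but does not state the grid) with `n_cycles` = f/2,
floored at 3, give log power in dB (10 log10); note `n_cycles` = f/2 makes
the temporal width $\sigma_t = 1/(4\pi)$ s identical at every frequency.
Baseline is the per-frequency mean over [-1.5, -1] s before onset,
subtracted in dB. Band powers are means over 8-32 Hz (LFB) and 76-100 Hz
(HFB) bins (closed intervals on bin centers) and the first 0.5 s after
onset.

# Region projection and group statistics

Right-hemisphere electrode positions are mirrored (x to -x). Electrode-to-
region weights are Gaussians of the 3D distance to each region point,
FWHM 20 mm ($\sigma$ = FWHM / (2$\sqrt{2\ln 2}$) = 8.4932 mm), summed over
the region's point cloud. Summed weights over electrodes give the region's
electrode density; regions whose subject-averaged density exceeds 3 are
retained (the same retained set is then used for every subject), and
retained regions' weights are normalized to sum to one. Bad channels are
excluded before weights are computed (the source does not state the order;
removal-first is assumed). The package does not ship an atlas: regions are
user-supplied point clouds, and a synthetic eight-region atlas generator
(canonical left frontoparietal/temporal locations) is provided for tests.

Group spectrograms are the median over events within subject, then the
mean across subjects. Masking compares each time-frequency bin with a
null built by resampling that frequency's baseline time points, two-sided
p with a +1/(n+1) continuity correction, Benjamini-Hochberg across all
bins of the region (per-region correction, matching per-panel masking; the
correction family is otherwise unstated), and non-surviving bins set to 0.
One deliberate deviation concerns what the bootstrap resamples. A null of
baseline *means* of the group plane is narrower than single-bin noise by
roughly $\sqrt{n_\text{baseline}}$ and would mark essentially every bin
significant under a global null; resampling the group plane's baseline
bins directly fares little better, because a discrete null supported on
~15 values cannot calibrate a thousand comparisons (about a quarter of
null bins survive). The calibrated construction - and what trial-level
baseline bootstraps in the EEG literature actually do - redraws one random
baseline time point per *event* and reapplies the full aggregation
(median over events, mean over subjects) per replicate, so each null draw
has exactly the sampling distribution of an aggregated bin. That is the
masking default (`event_planes`); the group-level variants (`block`)
remain available for single-plane use. The event-level null passes both
the global-null calibration (at most 1% survivors) and the 10 SD power
check.

# Behavioral features and regression

The ten per-event features: recording day and time-of-day bin (three 8 h
half-open bins starting at midnight); reach duration, magnitude (maximum
radial displacement from the onset position), vertically folded reach
angle (angles between 90 and 270 degrees reflected into [-90, 90], +90 up,
-90 down), and onset speed; a speech ratio (short-time 370-900 Hz power
over total power, 1 s windows with 0.5 s hop - the source does not state
the frame - optionally after a 40 dB spectral gate against a rest-noise
profile, smoothed by a first-order 4.2 mHz low-pass, averaged over
[-1, 1] s and clipped to [0, 1]); and three bimanual features (ipsilateral
share of summed reach magnitudes, temporal overlap of move states over the
contralateral dwell, and a binary class requiring at least four
consecutive ipsilateral move frames beginning within 1 s before onset or
during the dwell).

Regression (per electrode and band) follows the linear model
$y_{jkf} = \beta_{0kf} + \sum_i \beta_{ikf} x_{ij}$: continuous features
standardized on training rows only (duration and magnitude
log-transformed first), categorical blocks one-hot with one reference
level dropped (the intercept stays, avoiding the collinearity a full
one-hot would create), Huber loss minimized by IRLS with MAD scale
(delta 1.345, the standard 95% efficiency constant; the source does not
state one), greedy forward selection by positive adjusted-R-squared gain
of an OLS fit with categorical blocks entering atomically, repeated
day-balanced 90/10 splits (per-day test count max(1, round(0.1 n)); days
with fewer than two events stay in training), withheld-data R-squared, and
shuffle importance: one permutation of a retained feature's training
values per split, refit, R-squared on the untouched withheld rows,
subtracted from the full-model value. Features not retained in a split
contribute zero importance and zero coefficient for that split, and all
quantities are averaged over exactly `n_splits` splits with retention
frequencies reported.

# The synthetic world

The generator states the emulated recording once: 30 frames/s video,
1000 Hz neural sampling (500 Hz accepted directly where preprocessing is
exercised separately), rest dwells averaging 60 frames and move dwells 45
(negative binomial, `size` 5); rest dwells are shifted to at least 1.5 s so
each pre-onset baseline lies in rest, and move dwells to at least 0.5 s so
every configured movement is a detectable event. Reach magnitudes are
right-skewed (log-normal, median 60 px, floored at 15 px and capped at
250 px) and reach angles bimodal at ±90 degrees, matching the qualitative
shapes the source reports; 90% of movements have parabolic radial
profiles (the rest are jittery random walks that fail the quadratic
screen); positions carry 0.3 px jitter everywhere plus 1 px extra during
movement - wrists in motion are tracked less precisely, and real reaches
are never purely radial, so within-move velocity stays away from zero.
Confidence is high (Beta(20, 2)) with 2% of frames dipping low to
exercise pruning. Ipsilateral co-movements (40% of events) vary in lag,
length, and size so the three bimanual features correlate (about
0.8-0.9) without being collinear. Audio is a broadband floor with
band-limited 370-900 Hz bursts (or a pure 500 Hz tone for closed-form
checks) inside non-overlapping speech intervals.

Neural recordings are independent 1/f ("pink") backgrounds per channel,
scaled so the passband log PSD sits comfortably above the 0 dB
segment-rejection threshold (about +4.5 dB after preprocessing). For each
event, the 0.5 s after onset multiplies the 8-32 Hz and 76-100 Hz
band-limited components of motor channels by gains sized so the
*measured* band-averaged log-power change equals
$\beta_0 + \sum_i \beta_i x_i$ plus Gaussian noise (`noise_sd`, default
0.5 dB). Because the Morlet measurement smears the 0.5 s boxcar epoch, a
raw injection recovers only a fraction of the nominal dB change; this
fraction (0.785, identical for both bands because $\sigma_t$ is constant
across the grid) was calibrated once on clean injections and pinned as a
package constant. Non-motor channels receive no effect.

What the generator does *not* emulate: epileptiform or artifactual
transients beyond the synthetic spikes used in preprocessing tests,
volume conduction or cross-channel correlation, camera occlusions beyond
confidence dips, 3D kinematics, or photorealistic pose error structure. A
green end-to-end test therefore establishes that the pipeline's
statistics recover the stated generative structure - not that they would
be unbiased on clinical recordings.

# Numerical choices and limitations

* Measurement noise of single-event band power is about 1.6 dB (set by
  the number of effectively independent time-frequency samples in a band
  window), far above the generator's 0.5 dB residual. Coefficient
  recovery to ±0.1 dB is therefore asserted on averages across the ten
  seeded replications the recovery criterion prescribes, and day-offset
  coefficients are the slowest to converge (day-level averages of
  measurement error shrink only with events per day).
* Forward selection by adjusted R-squared is a weak filter (a block
  enters when its F exceeds roughly 1), so spurious features are retained
  in a sizable share of splits; their averaged coefficients and
  importances still shrink toward zero because signs vary across splits.
* Zero-phase filtering is implemented as linear-phase FIR with
  group-delay removal and odd-reflection padding; edge seconds of
  spectrograms (one wavelet length) are flagged unreliable.
* The dwell-law M-step optimizes a truncated negative binomial by
  Nelder-Mead from the current iterate and only accepts improvements, so
  EM monotonicity is preserved even when the optimizer stalls.
* Viterbi and the likelihood treat the final dwell as right-censored;
  the enumeration oracle in the tests scores segmentations under exactly
  the same convention.
* The per-day top-200 cap breaks onset-speed ties by earlier onset time;
  all orderings in the package are deterministic under a master seed, and
  the pipeline derives per-stage seeds from it.
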