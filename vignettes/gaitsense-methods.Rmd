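---
title: "Methods: smartphone 6MWT gait analysis and fall-risk classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone 6MWT gait analysis and fall-risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`gaitsense` turns a six-minute walk test (6MWT) recorded by a
pelvis-mounted smartphone into a binary fall-risk classification for
lower limb amputees. The underlying assumptions are those of
pelvis-level accelerometry: each foot strike produces an
anterior-posterior (AP) acceleration peak followed closely by a
vertical acceleration peak; step timing is quasi-periodic within a
trial; and 180° turns at the hallway ends are brief episodes of high
vertical-axis rotation rate during which step mechanics are atypical
and step windows should not contribute features.

The pipeline is: resample to 50 Hz → zero-lag 4 Hz low-pass → per-frame
foot-strike labelling → post-processing corrections → 62 features per
step → 248 features per participant → correlation-based feature
selection (CFS) + random forest under leave-one-out cross-validation
(LOOCV).

# Signal preprocessing

Raw app exports have slightly irregular timestamps; every channel is
linearly interpolated onto the grid `t0 + k/50` s. The low-pass filter
is a fourth-order zero-lag Butterworth with a 4 Hz cutoff, applied to
all signal channels (linear and raw acceleration, angular velocity and
the orientation angles — whether orientation should be filtered is a
genuinely open choice; filtering everything keeps the channels
mutually consistent and is configurable in principle through
`filter_spec()`).

*Numerical realization.* A forward-backward pass of a discretized
(bilinear-transform) Butterworth filter does not reproduce the analog
Butterworth gain at frequencies approaching Nyquist: at 8 Hz with a
4 Hz cutoff and 50 Hz sampling, frequency warping drags the realized
gain to 0.0023 instead of the canonical
$|H(f)|^2 = 1/(1 + (f/f_c)^8) = 1/257$. `lowpass_zero_lag()` therefore
applies the squared Butterworth magnitude response exactly in the
frequency domain after odd-reflection padding of $3(\mathrm{order}+1)$
samples. This is zero-phase by construction, matches the canonical
response at every frequency, preserves constants exactly, and behaves
as an identity when the cutoff is far above Nyquist. The warm-up
requirement is the padding length: series must exceed
$3(\mathrm{order}+1)$ samples.

# Foot-strike detection

Two detectors produce per-frame labels (0 = no strike, 1 = strike):

**Rule-based** (`label_rule_based()`): AP local maxima above 20% of
the trial maximum, separated by at least the locking period, become
events when a vertical local maximum follows within 0.1 s. The 20%
floor rejects filtered noise ripple while keeping the
amplitude-suppressed steps inside turns; the 0.1 s pairing window
matches the AP-to-vertical pulse delay of pelvis accelerometry (60 ms
in the simulator).

**Trainable** (`train_detector()` / `detect_frames()`): a per-frame
sequence labeller over a sliding window of ±5 frames (0.2 s) of all
twelve signal channels. The labeller is a class-weighted random forest
(100 trees, positives up-weighted by the negative/positive frame
ratio, fixed seed, single-threaded for reproducibility). A recurrent
network is the obvious alternative; a windowed forest was chosen as
the package's own design because the discriminating information for a
strike frame is local (the pulse shape spans well under 0.2 s), the
model trains in seconds on a CPU, and its predictions are exactly
reproducible. Any sequence labeller meeting the same held-out bar
could be substituted behind the same interface. Degenerate training
sets with a single class yield a constant model (documented
behaviour), and recordings shorter than the window are handled by edge
replication.

# Post-processing corrections

Predicted labels carry two error modes: extra predictions and missed
steps.

* **Duplicate collapse**: each maximal run of consecutive 1-labels
  becomes one event at the frame of maximum AP acceleration within the
  run (earliest frame on ties).
* **Adaptive locking period**: from the first 5 s of filtered vertical
  acceleration, the dominant step period is the smallest
  autocorrelation-peak lag with autocorrelation above 0.2 and lag of
  at least 0.24 s (shorter lags would imply a step rate above ~4 Hz,
  outside human walking). The locking period is half that period,
  clamped to [10, 35] frames; signals with no qualifying peak (e.g.
  white noise) fall back to the lower clamp. Events closer than the
  locking period are thinned, keeping the larger AP value.
* **Missed-step insertion**: a gap longer than 1.5× the preceding step
  duration (the first gap is compared against the trial-median
  interval, since no preceding step exists) is searched for a missed
  strike. The search range is shrunk by half the locking period at
  both ends, and the candidate must be an AP *local maximum* at least
  one full locking period from both neighbours — requiring a genuine
  peak prevents insertion into featureless stretches, and the
  neighbour margin guarantees the output events stay at least a
  locking period apart. The scan repeats until no qualifying gap can
  be filled; it terminates because every pass inserts an event and
  events are bounded below in spacing.
* **Side assignment**: strikes alternate; the first side comes from
  the sign of the medio-lateral acceleration at the first strike
  (negative = leftward sway = left strike), falling back to `unknown`
  for flat ML signals, in which case downstream temporal features use
  alternating pseudo-sides and flag the result.

# Features

Step windows span consecutive strikes of either foot (half-open in
frames); strides span same-side strikes, so a step's stride time is
its duration plus its neighbour's. Cadence is computed per step
(60/step time) so that all 62 features aggregate the same way. The
symmetry index uses the step and its neighbouring step:
$SI = |t_R - t_L| / (0.5 (t_R + t_L)) \times 100$.

Turn windows (mean |vertical-axis rotation rate| > 45°/s) are excluded
by default; 45°/s sits midway between straight-walking pelvic rotation
(< 10°/s) and a 2 s, 180° turn (90°/s). Temporal attribution happens
before exclusion so neighbour durations remain physical.

Spectral features are computed from the single-sided magnitude
spectrum of the mean-removed window, zero-padded to 256 samples
(≈ 0.2 Hz resolution at 50 Hz; windows are 20–60 frames, so padding
dominates and the grid is common to all steps). The named statistics
are defined as: quartile FFT = 25th percentile of magnitudes, maximum
FFT = largest magnitude, SD FFT = standard deviation of magnitudes,
peak distinction = (max − mean)/max (0 for an all-zero spectrum), and
REOH = even-harmonic power over total harmonic power at integer
multiples of the step frequency up to Nyquist, each harmonic read from
its nearest bin. These formulas are this package's choices — the
feature *names* are standard, their exact definitions are not — and
scale as documented: doubling a channel doubles magnitude statistics
and leaves peak distinction and REOH invariant.

Aggregation uses the sample (n−1) standard deviation and requires at
least two steps. The registry order of the 62 step features and the
248 participant features is fixed and exported
(`feature_registry()`, `participant_registry()`); CSV headers follow
it verbatim.

# Classification

CFS scores a subset of $k$ features as
$M_S = k \bar r_{cf} / \sqrt{k + k(k-1) \bar r_{ff}}$ with
point-biserial feature-class and Pearson feature-feature correlations
(the discretized symmetric-uncertainty variant is the main
alternative; Pearson was chosen because all 248 features are
continuous and the labels binary). Zero-variance features correlate 0
with a warning. The best-first forward search starts from the best
singleton and stops after 5 consecutive non-improving expansions, with
ties broken by registry order so selection is deterministic.

CFS runs *inside* each LOOCV fold, on the n−1 training participants
only — selection on the full data would leak the held-out label. Each
fold trains a 100-tree random forest (`sqrt(d)` candidate features per
split, majority vote, per-fold seed) on the selected features and
predicts the held-out participant; the n predictions fill the
confusion matrix (rows actual, columns predicted, fall risk positive).
Metrics are exact ratios, rounded to one decimal only for percentage
display.

# The synthetic gait generator

`generate_walk()` emulates what the detection and feature chain
needs from amputee 6MWT data, not amputee biomechanics: per-step
Gaussian AP and vertical pulses (σ = 50 ms, vertical delayed 60 ms)
at grid-snapped strike times; stride-frequency sinusoidal ML sway
phase-locked to the strike schedule; step-time asymmetry as a
right/left ratio splitting the cadence-determined mean step time;
180° turns every `hallway_length / walk_speed` seconds with ramped
rotation angle, elevated gyro rate and half-amplitude step pulses;
and additive white noise on every channel. Defaults are the study
conditions: 360 s, 50 Hz, 20 m hallway; cadence 110 steps/min and
noise 0.15 m/s² are mid-range walking values chosen once as
realistic.

`generate_cohort()` draws per-member cadence, asymmetry and noise
from class-conditional normal distributions; the default 27/53
fall-risk split matches the clinical cohort size, and the default
class separations (cadence 88 vs 106 steps/min, asymmetry 1.18 vs
1.05, noise 0.25 vs 0.15 m/s²) encode the expectation that fall-risk
gait is slower, more asymmetric and noisier — roughly a 2-SD
separation on each axis.

What the simulator does **not** model: prosthetic-specific waveform
morphology, double-peaked or poorly defined AP peaks, gait-aid
artefacts, drift, or missing data. Passing tests therefore demonstrate
that the chain is correct under its stated signal model, not that
clinical accuracy would match; the published clinical confusion
matrices are used directly where clinical numbers are needed.

# Problem sizes and determinism

Tests and the acceptance script use 60 s walks for detector training
(21 walks: 20 train, 1 held out) and full 360 s walks for the
80-member end-to-end cohort — sizes chosen so the whole suite runs in
minutes on one CPU while keeping the cohort at the study's scale.
Every stochastic step (generator, cohort draws, forest training,
per-fold seeds) is driven by explicit integer seeds; identical seeds
give bit-identical recordings, models and reports.

# Known limitations

* Side assignment from ML sway assumes the sway sign convention holds;
  a phone mounted upside-down would swap sides (the alternation itself
  is unaffected).
* The locking-period estimate needs 5 s of reasonably periodic walking
  at trial start; trials beginning with standing still fall back to
  the clamp bound.
* Frame quantization at 50 Hz bounds the symmetry index resolution at
  roughly 4% for 0.5 s steps.
* The symmetric-uncertainty CFS variant and event-wise (rather than
  frame-wise) detection metrics are not implemented.
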