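---
title: "Methods: subject-independent emotion recognition from peripheral physiology"
author: "physioemo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subject-independent emotion recognition from peripheral physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Peripheral physiology — the electrocardiogram (ECG), electrodermal activity
(EDA, skin conductance) and skin temperature (ST) — carries information about
a person's emotional state, conventionally described by two binarized
dimensions: valence (unpleasant/pleasant) and arousal (calm/excited), giving
four joint classes. Two obstacles make deployment hard:

* **Subject dependence.** Resting heart rate, skin conductance baseline and
  gain, and skin temperature differ widely across people, so a classifier
  trained on some subjects degrades on new ones.
* **Environment (sensor-brand) shift.** A different recording device imposes
  an approximately affine transformation on each channel (gain and offset),
  so a model trained in one lab degrades in another even for comparable
  subjects.

`physioemo` implements a complete, tested pipeline addressing both: fixed
physiological feature extraction, an automatic feature-calibration model that
translates a new subject's features toward the most correlated training
subject, and a cellular-neural-network (CNN, in the Chua–Yang sense of a
lattice of coupled dynamical cells — not a convolutional network) classifier
trained in the echo-state fashion with a ridge-regression readout. Because no
public recording set ships with the package, a first-class synthetic
generator produces class-conditioned multi-sensor trials on which every stage
is exercised and tested.

## Feature extraction

Signals are brought to fixed rates (ECG 256 Hz, EDA and ST 4 Hz) and each
trial becomes a 25-dimensional vector:

* **EDA (12).** The signal is split into the tonic skin conductance level
  (SCL: zero-phase Butterworth low-pass, 0.05 Hz cut-off, order 3, reflection
  padding) and the phasic residual, so `scl + phasic` reconstructs the input
  exactly. SCL contributes mean, SD, max, min, RMS, mean first and second
  difference, and the mean over negative first-difference samples only.
  Skin conductance responses (SCRs) are detected trough-to-peak on the phasic
  signal; an event is significant if its rise is at least 0.05 µS
  (configurable) *and* its peak stands above the tonic line by half that
  threshold — the latter suppresses the rebound artifact a subtractive
  decomposition leaves after each response. Features: SCR rate per minute
  (counted after band-limiting the phasic signal to 0–0.1 Hz, merging ripples
  into discrete events), first-SCR latency (trial duration if none), and the
  sums of amplitudes and areas (trapezoidal integral above the trough level
  to recovery at half amplitude). Amplitude-bearing features are measured on
  the *unfiltered* phasic signal: the biexponential SCR shape (1 s rise, 4 s
  decay) keeps only about a quarter of its energy above 0.05 Hz, so any
  band-limited amplitude would systematically underestimate the response.
* **ECG (8).** R peaks are detected Pan–Tompkins-style (band-pass 5–30 Hz,
  squaring, 150 ms moving-window integration, adaptive threshold, 200 ms
  refractory). Beat-to-beat (NN) intervals outside (200, 3000) ms are
  dropped. Time domain: mean NN, SDNN, RMSSD, NN50, pNN50. Frequency domain:
  the tachogram is linearly interpolated to 4 Hz and a Welch PSD computed
  (Hamming windows of 64 s, 50% overlap); LF power is the mean PSD over
  0.04–0.15 Hz, HF over 0.15–0.4 Hz, plus their ratio. The spectral features
  require about a minute of beats; the gate is set at 55 s because a 60 s
  recording's NN series necessarily spans slightly less than 60 s.
* **ST (5).** Mean, max, SD, min and mean first difference. A 3-feature mode
  (the central moments only) is available via
  `feature_config(st_extended = FALSE)`; the 5-feature set is the default
  because the feature inventory this pipeline follows counts five ST
  features, and because the first-difference statistic is what carries slow
  vasomotor trend information.

## Automatic feature calibration

**Offline.** For each training subject, trial vectors are clustered by
G-means: start with one cluster, and repeatedly replace any cluster whose
members fail a Gaussianity test by its two 2-means children (k-means++
seeding, cosine assignment distance, arithmetic-mean updates), with a global
refinement after each round, until every cluster passes or a cap of 16 is
reached. The Gaussianity test projects the members onto their principal
component, standardizes, and applies the Anderson–Darling normality test at
α = 0.10; clusters under 8 members are accepted. Two calibrated choices
deserve note. First, the projection uses the principal component rather than
the realized 2-means children direction: the children direction is chosen to
maximize separation and makes the test anti-conservative on genuinely
Gaussian clusters (measured acceptance 0.83 vs 0.87 at n = 100), while the
principal component of bimodal data is the mode-split direction, so power is
unaffected. Second, the test's randomness is keyed to the cluster's
membership, so a cluster that is stable across refinement rounds receives one
verdict rather than a fresh draw per round — repeated testing would otherwise
inflate the split rate far above α. Each final cluster stores its centroid,
its per-dimension SD vector, and its member count.

**Scaling.** Before clustering and matching, features are mapped to
comparable scales by global training **min-max normalization** (each feature
to [0, 1]). The choice matters more than it looks. The matching rule selects
the centroid with the highest *absolute* Pearson correlation |r| computed
across the feature dimensions. In a *centered* space (z-scores), the four
emotion classes form two axes, so the opposite class anticorrelates as
strongly as the same class correlates: measured on the synthetic benchmark,
54–90% of |r|-matches were strongly negative and calibration *reduced*
accuracy from 65% to 34%. In raw units the common magnitude shape (hundreds
of ms next to microsiemens) drives every correlation to ≈ 1.00 and matching
becomes uninformative. Min-max keeps scales comparable while keeping vectors
in the positive orthant, where correlations stay predominantly positive
(measured: 0% negative matches) and |r| behaves as the similarity search it
is meant to be.

**Online.** Each test vector is normalized with the training scaler, matched
to the best-|r| centroid over all clusters of all training subjects (exact
ties broken lexicographically), and translated toward it. Two translation
modes exist because the printed normalized-translation arithmetic
(`dn = (d·1 − C)/σ`, `Vnew = V − dn`, with `d` the Euclidean distance) does
not map `V = C` to itself; it is provided verbatim as `mode = "literal"`. The
default `mode = "directional"` implements the stated intent — move toward the
centroid without overlapping it — as `Vnew = C + σ ⊙ (V − C)/d`, which keeps
the offset direction and sets its per-dimension length to one cluster SD
(`V` itself if `d = 0`). For isotropic σ the SD shell is an exact fixed
point; for anisotropic σ the calibrated distance lies between `min(σ)` and
`max(σ)`, and the translation strictly contracts whenever `d > ‖σ‖`. Results
are mapped back to raw feature units, so calibrated tables are
plug-compatible with the classifier.

## The classifier

Each sensor's feature block drives its own lattice of n coupled cells,

    dx/dt = −x + A·tansig(x) + B·u + bias,     tansig(x) ≡ tanh(x),

integrated by explicit Euler (step 0.5, zero initial state, input held
constant, 20 steps with early stop when the update falls below 1e−8; the
input is constant, so the state approaches a fixed point and the final value
is held). Templates follow the echo-state recipe and are never trained:
A is sparse (entries zero with probability 0.5, applied to the upper triangle
and mirrored so the realized zero fraction stays at 0.5) symmetric N(0, 1),
divided by its largest absolute eigenvalue (spectral radius exactly 1);
B and the bias are N(0, 1) scaled by 0.1. The three reservoirs' outputs are
multiplexed in fixed sensor order with a constant 1 appended, and the only
trained component is the linear readout onto the four one-hot class targets:

    A_global = G Yᵀ (Y Yᵀ + β I)⁻¹,

solved as a linear system. Predictions are argmax over the four outputs
(ties to the lowest index). Features are z-scored on training statistics
inside the model; the cell count n and ridge coefficient β are selected by
subject-grouped cross-validated grid search (default grid
n ∈ {50, 100, 150, 1000, 1500}, β ∈ {0.1, 0.01, 0.001, 1e−4, 1e−5};
ties prefer smaller n, then larger β), after which the readout is refitted
on all training data. Grouping folds by subject keeps model selection
subject-independent. Reservoir templates are redrawn per fold from
fold-derived seeds; the final model's templates are regenerated exactly from
stored seeds when a serialized model is loaded.

## The synthetic generator

The generator encodes the class structure the features must detect, with
arousal the stronger axis and valence the weaker one, mirroring the
empirical literature:

| Mechanism | Low | High |
|---|---|---|
| Mean heart rate (arousal) | 70 bpm | 85 bpm |
| RR jitter SD (arousal) | 40 ms | 18 ms |
| LF:HF modulation amplitude (arousal) | ≤ 1:2 | ≥ 2:1 |
| SCR Poisson rate (arousal) | 2/min | 8/min |
| Tonic EDA increment (arousal) | 0 | +1.5 µS |
| Mean ST shift (arousal) | 0 | −0.4 °C |
| SCR amplitude scale (valence) | U(0.1, 1) µS | +0.3 µS |
| ST thermal trend (valence) | −0.008 °C/s | +0.008 °C/s |

Per-subject effects are drawn once per subject: heart-rate offset U(−10, 10)
bpm, EDA gain U(0.7, 1.4) and baseline U(2, 8) µS, ST baseline U(31, 34) °C.
The ST valence effect is realized as a directional thermal trend (slow
peripheral warming under high valence, cooling under low, ~1 °C over a 2 min
trial) plus a random walk of SD 0.1 °C: a symmetric random walk whose sign
flips would be invisible to mean/max/SD statistics, so the trend is what
makes the designed effect observable. ECG is rendered as one Gaussian R spike
(1 mV, ~20 ms) per beat over 0.02 mV noise — deliberately minimal morphology;
the only property required is that a detector recovers the beat times.
Every generator is a pure function of its arguments: each trial's RNG stream
is derived from (seed, subject, trial) by a stable hash, so adding subjects
never perturbs existing subjects' data.

A recording-environment shift is modeled as per-channel affine maps of the
raw samples. The benchmark default (EDA gain 1.3, offset +2 µS; ECG gain
1.2; ST offset +0.8 °C) reflects that electrodermal electrodes differ most
across brands, temperature sensors disagree by fractions of a degree, and
ECG amplitude scaling is inert to timing-based HRV features.

What the generator does **not** emulate: realistic ECG morphology (P/T
waves), motion and electrode artifacts, respiration or any coupling between
channels beyond the shared class label, non-stationary emotion within a
trial, and the heavy-tailed inter-subject variability of real populations.
Passing tests therefore demonstrate that the pipeline recovers the designed
effects under controlled conditions — not field performance on real
recordings.

## Evaluation protocols and observed behavior

Three protocols, all subject-independent (no test subject contributes
training data): `same_env` (new subjects, same environment),
`cross_env_nocal` (new subjects recorded under the affine shift) and
`cross_env_cal` (the same shifted subjects after calibration against the
training profiles). The benchmark trains once per replicate and evaluates
all three. Reported metrics are accuracy plus macro one-vs-rest specificity,
precision and recall over the four classes (undefined ratios reported as 0
and flagged).

Problem sizes were chosen to keep a full 20-replicate benchmark around a few
minutes: 6 training + 3 test subjects, 16 trials each, 120 s trials, grid
n ∈ {50, 150}, β ∈ {1e−3, 1e−4}. `scripts/acceptance.R` recomputes the
headline quantities at these sizes; the direction of effect it demonstrates —
calibration recovers most of the accuracy a sensor-brand shift costs — is the
package's central claim, not any absolute accuracy, which at desk scale is
limited by the small training population.

## Known limitations

* The |r| matching rule remains blind to the *sign* of the relationship it
  exploits; min-max scaling makes negative matches rare rather than
  impossible, and neither mode flips the translation for a negative-r match.
* G-means at α = 0.10 splits liberally; on 16 trials per subject profiles
  often reach the small-cluster regime where the ≥ 8-member rule, not the
  test, stops splitting.
* With ~96 training trials the readout at β ≤ 1e−3 operates in the
  interpolation regime; cross-validated selection mitigates but does not
  remove the variance this causes.
* The Euler step 0.5 with spectral radius 1 is marginally stable by design;
  states remain bounded because the input is constant and tanh saturates,
  and integration aborts with a named error if a non-finite state ever
  appears.
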