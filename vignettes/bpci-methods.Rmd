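---
title: "Cuff-less blood pressure with per-subject intervals: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuff-less blood pressure with per-subject intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpci)
```

# The estimation problem

A cuff-less monitor observes a photoplethysmogram (PPG) and an
electrocardiogram (ECG) and must report systolic and diastolic pressure
(SBP/DBP, mmHg). The physics underneath is the pressure dependence of pulse
wave velocity: stiffer, more pressurized arteries transmit the ejection wave
faster, so the delay between the ECG R peak (a proxy for ventricular
ejection) and the arrival of the pulse at the periphery — the pulse transit
time, PTT — shortens as SBP rises. `bpci` treats the relation as locally
linear, `SBP = a − b · PTT`, and learns the full mapping from 47 waveform
descriptors to pressure nonparametrically. Because a single point estimate
hides the measurement's reliability, the pipeline's real output is an
interval per subject, built from the ~10 beat-segment estimates a 20-s
window provides.

# Pipeline stages and their parameters

## Windowing and label screening

Analysis uses a 20-s window taken 60 s into each record (2500 samples at
125 Hz). The 60-s offset skips settling transients; it is a configurable
default (`extract_window(start_s = 60)`) since nothing in the method depends
on its exact value. Reference labels outside (70, 200) mmHg systolic or
(40, 150) mmHg diastolic are excluded *inclusive of the boundary* — these
are outlier readings that would otherwise dominate a squared-error fit.

## Stage 1: denoising

Each channel is decomposed with a 10-level maximal-overlap discrete wavelet
transform (MODWT, db8). The MODWT is undecimated, hence length-preserving
and shift-invariant, which matters because downstream features are timing
measurements. Coefficient handling:

* **d1–d6** (≈1–62.5 Hz at 125 Hz sampling) are shrunk by empirical-Bayes
  posterior-median thresholding under a heavy-tailed (quasi-Cauchy) prior.
  The mixing weight is estimated per level by marginal maximum likelihood;
  the noise scale is estimated *once*, from the median absolute deviation of
  the level-1 coefficients, and propagated down as `sigma / 2^((j-1)/2)`
  (white-noise detail variance halves per level). Estimating the scale per
  level instead would read coherent signal at the coarse levels as noise and
  annihilate it — an instructive failure mode we guard against in tests.
* **d7–d10 and the approximation a10** (≈0–1 Hz) are zeroed: baseline
  wander, respiration and DC live there. The window boundary is handled by
  reflection (the input is mirrored before the circular transform) to avoid
  wrap-around artifacts in 20-s windows.
* A zero-phase high-pass (Butterworth, 0.5 Hz cutoff, order mapped from a
  "steepness" parameter in [0.5, 1], applied forward–backward via
  `filtfilt`) removes what drift remains. Zero-phase application is
  deliberate: a causal IIR pass would delay fiducial points by a
  frequency-dependent amount and bias every PAT/PTT feature. A one-pass mode
  exists behind `one_pass = TRUE` for users who want the conventional causal
  response.

One consequence worth knowing: zeroing d7–d10 removes the 0.5–1 Hz band, so
for heart rates below ≈60 bpm part of the cardiac *fundamental* is
discarded and the denoised PPG is carried by its harmonics. The fiducial
detector is built to survive this (below), but repeated application of the
denoiser re-attenuates band-edge content — the denoise+high-pass pair is
idempotent to well under 5% relative L2 only for pulse spectra away from the
d6/d7 boundary. The test suite checks idempotency at 75 and 90 bpm for this
reason.

## Stage 2: fiducial detection and segmentation

R peaks: the ECG is re-decomposed with a 4-level sym4 MODWT and
reconstructed from detail levels 2–3 only — the 8–30 Hz band where an 80-ms
QRS lives — then a three-point peak search runs on the rectified
reconstruction with an adaptive threshold (half the rolling 98th percentile
over 2-s blocks; the "empirically determined threshold" is not specified
anywhere more precisely, so this package fixes a formula and exposes it) and
a 0.3-s refractory period.

PPG fiducials: peaks are detected on a lightly smoothed trace (0.15-s moving
average) and refined to the raw local maximum, with a secondary-peak
suppression pass that removes dicrotic bumps (any interval under 0.55× the
median beat interval drops the smaller peak). Feet are the minima between
peaks; the maximum-slope point is the first-difference argmax on the rising
limb; the diastolic inflection is the first upward zero-crossing of the
second difference after the peak, with a fallback to the 34%-of-amplitude
decay point (flagged `fallback`) when no crossing exists. The zero test is
scaled by pulse amplitude so floating-point dust on piecewise-linear pulses
cannot fake a curvature crossing.

Trusted windows are cut into beat-anchored segments of `round(1.4 · fs)`
samples starting at each pulse foot, capped at 13; fewer than 10 segments
rejects the window (reason `min_segments`) rather than erroring, because in
a cohort run a rejected window is data loss, not a bug.

## Signal-quality index

Three rules run first, on *both* the ECG and PPG beat trains (strict joint
reading — both channels must pass): extrapolated heart rate in 40–180 bpm;
no inter-peak gap above 3 s; max/min interval ratio under 2.2. The printed
unit of the third rule is a ratio, not seconds. Any failure short-circuits
to *untrusted*. Otherwise each beat (a window of the median beat interval,
centered on its peak; edge-truncated beats excluded rather than zero-padded)
is correlated with the mean-beat template, on the PPG and on the
QRS-enhanced ECG, and the window is trusted iff the mean of the two mean
correlations reaches `corr_threshold`.

`corr_threshold = 0.8` is the single largest constant this pipeline needs
that no source states. It is exposed prominently and should be recalibrated
for any new sensor; raising it can only shrink the trusted set
(monotonicity is tested).

## Features

The 47 descriptors follow the field's standard catalogue; each is computed
on the baseline-shifted pulse (minimum set to zero) so that normalized
amplitude features are translation invariant. Definitions that required a
package-level decision:

* **PTT** is operationalized as PAT2 (R peak to maximum-slope point) minus a
  configurable pre-ejection constant, default 0. A cuff-less system has no
  aortic-valve signal, so true transit time is not observable; pulse
  *arrival* time stands in for it. PTT is emitted as an auxiliary column,
  not one of the 47 (the canonical table defines exactly 47 without it).
* **PIR** is computed as peak-over-mean amplitude of the shifted pulse. The
  classical peak/trough intensity ratio is undefined after DC removal (the
  shifted trough is exactly zero), so this is a provisional reading chosen
  to stay finite and translation invariant.
* **MEU** ("blood viscosity") and **FHR** ("heart-rate frequency") are
  under-defined in their source; they ship as the pulse-amplitude decay
  ratio two-thirds into diastole and the dominant periodogram frequency of
  the segment, and are marked provisional.
* **MCORR** (max PPG–ABP cross-correlation) needs the arterial line and so
  exists only for training data; at inference it is imputed with the
  training median. Because it is the one feature that touches the label
  channel, it can be disabled (`with_abp = FALSE`) when leakage is a
  concern.
* **Entropy** is the Shannon entropy (nats) of a 16-bin amplitude histogram
  of the normalized pulse; widths SW/DW are measured at amplitude fractions
  (10/25/33/50/66/75%) on the rising and falling limbs, the reading
  consistent with horizontal width lines on a pulse diagram.

Reference pressures average the per-beat extrema of the ABP segment, after
a 40-ms moving average: the raw max of a noisy trace is a biased estimator
(noise inflates maxima and deflates minima), and the smoothing removes most
of that bias at negligible cost to the true peak.

## Feature selection: MRMR + weighted feature decision

MRMR ranks features by the mutual-information quotient MIQ = relevance /
redundancy, with mutual information estimated by a plug-in estimator on
10×10 equal-frequency (rank-based) contingency tables — deterministic,
fast, and invariant to monotone rescaling of the features. Zero tests on
estimated MI use a 1e-12 tolerance, and the zero-relevance tail is appended
in ascending index order (a seeded shuffle is available for fidelity to the
original procedure's "random order").

The weighted feature decision then scores every prefix of the ranking by
5-fold cross-validated MSE of the gradient-boosting engine (50 stages,
depth 2, shrinkage 0.1) and keeps the prefix with the smallest mean CV
error, ties toward fewer features. One fold partition, fixed by the seed,
is shared across all prefix sizes so that the comparison between sizes is
not confounded by partition noise; per-size repartitioning (the original
formulation) is available behind `repartition = TRUE`.

## Gradient boosting

The regression engine is written from scratch: stagewise additive trees fit
to the residuals of squared-error loss, exact greedy splits minimizing the
weighted two-sided SSE around side-wise weighted means, deterministic
tie-breaking (smallest feature index, then smallest threshold), and a unit
exact line search applied with shrinkage. Convolutional split functions for
image-structured inputs are out of scope — the inputs here are tabular.
The single-stump case is verified against an exhaustive split-search oracle
in the tests.

## Gaussian process regression

The default kernel is the absolute exponential with one isotropic length
scale, a distinct signal variance, and additive noise; the
squared-exponential is available. Keeping signal and noise variance
separate is essential — collapsing them makes the marginal likelihood
degenerate. Fitting maximizes the log marginal likelihood in log-parameter
space by L-BFGS-B with analytic gradients (envelope theorem handles the
profiled basis weights), 5 restarts scattered around data-driven initial
values (length scale = median pairwise distance; noise = 10% of target
variance). All linear algebra goes through one Cholesky factorization per
objective evaluation; a small jitter (1e-8) keeps it positive definite.
Inputs and the target are standardized by default; predictions are returned
on the original scale.

The mean-absolute-error-optimal point prediction is the posterior median,
which for this Gaussian predictive distribution coincides with the mean —
the package documents rather than duplicates this.

A note on identifiability: for the exponential (Ornstein–Uhlenbeck) kernel
on a fixed domain, only the ratio of signal variance to length scale is
strongly identified; individual recovery of all three hyperparameters is a
well-posed check only for the smoother squared-exponential kernel, which is
what the parameter-recovery test uses.

## Uncertainty constructions

Given a subject's n segment-level estimates:

* **Type A** standard uncertainty `u = sd/sqrt(n)` (n−1 denominator).
* **Expanded uncertainty** `U = K · u_c`,
  `u_c = sqrt(u_alpha^2 + u_beta^2 + u_gamma^2)`; `u_gamma = 1 mmHg` is the
  maximum allowable error of a mercury-sphygmomanometer reference and gives
  the interval a 4-mmHg width floor at `K = 2` (reported level 0.95).
  `u_beta` (bias) defaults to 0 and is estimated as the mean
  estimate-minus-reference difference when calibration data exist. An
  alternative reading `u_alpha = sd` is available (`uncer_sd = TRUE`);
  which components entered the original construction is not stated, so
  neither reading is asserted as canonical.
* **Parametric bootstrap**: Gaussian MLE (n-denominator SD), an `n × B`
  matrix of redraws, column means, percentile interval. `B = 1000` by
  default (unstated in the source; configurable). The per-column statistic
  is deliberately the *mean*, making this a CI for the subject's mean
  estimate.
* **Central-limit interval** `mean ± z · s/sqrt(n)`.

Interval widths outside 7–10 mmHg (SBP) or 3–6 mmHg (DBP) trigger an
informational message — the band considered clinically sensible — never an
error.

A point about what these intervals estimate: the bootstrap and
central-limit constructions are intervals for the subject's *mean pressure
over the beats that were actually measured*. That is the natural measurand
for a 20-s reading — per-beat pressure drifts within the window, and beats
the segmenter never used are outside the measurement. Coverage checks in
the test suite and the acceptance script therefore compare each interval
against the true mean of the matched beats, not against a whole-window
average the estimates never saw.

# The synthetic generator

`generate_record()` builds a beat schedule (Gaussian interval jitter around
the target heart rate), draws per-beat SBP as a slow sinusoidal drift plus
noise, derives per-beat PTT exactly from `SBP = a − b·PTT`, and renders:

* ECG — a biphasic 80-ms QRS template at each R time (so the sym4 d2–d3
  band captures it);
* PPG — a two-bump pulse (systolic wave + smaller dicrotic wave) whose foot
  trails its R peak by that beat's PTT, on a positive optical baseline;
* ABP — an intra-beat shape that attains exactly the drawn SBP and DBP, so
  ground truth and channel extrema agree to well under 0.1 mmHg.

Injectable artifacts: white noise, baseline wander, motion spikes (single or
trains), dropped beats (flattened stretches that open a > 3-s gap), and
polarity-inverted beats (flipping both the optical pulse and the co-located
ECG stretch, as a sensor-polarity fault would). Identical profile and seed
give bit-identical records; all randomness flows through one local RNG that
never touches the global stream.

Cohorts (`generate_cohort()`) share a single coupling line
(`a = 167 mmHg, b = 150 mmHg/s`, so baseline PTT spans ≈0.11–0.45 s across
a 100–150 mmHg SBP range) — between-subject pressure differences are
carried by transit time exactly as within-subject ones, which is what makes
the mapping learnable on held-out subjects. Default conditions for the
end-to-end runs: 50 subjects, heart rates 55–95 bpm, reference-channel
noise SD 2 mmHg, within-subject SBP SD 4 mmHg, pulse pressure 40 ± 1.5
mmHg. These are realistic magnitudes for short resting recordings; they
were chosen once, up front.

What the generator does **not** emulate: real pulse morphology classes
(aging, arrhythmia, damping in the arterial line), motion artifacts with
physiological structure, drug-driven hemodynamic transients, sensor
saturation, or any nonlinearity in the PTT–pressure relation. Passing the
end-to-end tests therefore demonstrates that the pipeline's machinery is
correct and internally consistent at clinical noise scales — not that the
method achieves any particular accuracy on hospital waveforms.

# Numerical choices and degenerate inputs

* MODWT: reflection boundary; perfect reconstruction is tested to 1e-10.
* Cauchy posterior median: vectorized bisection (40 iterations); the
  `|z| ≥ 20` branch uses the asymptotic form `z − 2/z`; values below 1e-7
  snap to zero (it is a genuine thresholding rule).
* Flat pulses (`ps == pd`) raise a degenerate-pulse error; constant ABP is
  a no-beat rejection; fewer than 2 peaks is an insufficient-beats error
  with a machine-readable class.
* Split search: ties in SSE resolve to the smallest feature index, then the
  smallest threshold, making WFD bit-reproducible.
* GPR: log-parameter bounds ±15, jitter escalation is not needed in
  practice because standardization keeps the problem well scaled; the
  predictive variance is clamped at zero.
* Bootstrap with zero spread returns the degenerate interval `(mean, mean)`
  rather than erroring — repeated identical readings are legal input.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale: 20-s windows, cohorts of 10–50 subjects (≈110–600 beat
segments), 10,000-replication coverage simulations, 20-seed recovery
studies at n = 200–300, and oracle comparisons at n ≤ 64. These sizes were
chosen to exercise every code path and statistical property at high power
while keeping a full run in minutes on one core.

# Known limitations

* PAT is used in place of PTT (no pre-ejection-period signal); the
  constant-offset correction is exposed but defaults to 0.
* The SQI correlation threshold (0.8) and the adaptive-threshold formula
  for peak search are package-fixed constants; both are exposed, neither is
  externally validated.
* MCORR at inference time is an imputed constant; disable ABP-derived
  features entirely for strict leakage hygiene.
* Grading helpers implement the strict all-tiers BHS rule; a cumulative
  triple that fails a tier grades into the band below it even if the
  headline column looks better.
* Exact GPR is O(n³); the subset-of-data switch is a plain row subsample,
  not a sparse approximation.
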