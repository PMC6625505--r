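---
title: "Methods: event classification, quality metrics, and the pursuit hinge model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event classification, quality metrics, and the pursuit hinge model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeqc)
```

# Scope

`gazeqc` analyses multi-task eye-tracking test batteries in which the same
gaze is recorded simultaneously by two trackers — typically a stationary
research-grade device sampling at a constant 500 Hz (or 250 Hz) and a mobile
glasses-type device whose gaze stream is fused from two 120 Hz eye cameras.
The package covers the full path from raw sample streams to group-level
quality statistics: clock synchronization, bad-sample exclusion, pixel to
spherical-degree conversion, classification of blinks, saccades,
microsaccades and fixations, spatial accuracy and precision with winsorized
aggregation, a Bayesian hinge model of smooth-pursuit onset, pupil-area
normalization, and the battery's schedule generators. A synthetic
dual-tracker simulator supplies ground truth so that every stage can be
validated by parameter recovery rather than by eye.

# Coordinate geometry

Screen positions are converted per axis from pixels (origin at the screen
center) to spherical visual degrees with

beta = 2 * atan2(p * m, d),

where `m` is the pixel pitch in mm/px and `d` the viewing distance in mm.
This is the form used operationally throughout the package
(`angle_formula = "as_printed"`). Note that the conventional visual-angle
expression places `2d` in the denominator; for offsets under 2 degrees the
two differ by a factor approaching 2. Because published grid extents cannot
disambiguate which form produced a given dataset (margins are unknown), the
conventional form is available as `angle_formula = "half_offset"`, and the
choice is carried in the `screen_geometry` object so downstream output can
record it. Comparisons between datasets are only meaningful under a single
consistent choice.

Angular distances are cosine (great-circle) distances between gaze
directions expressed as Cartesian unit vectors in a frame rotated so the
screen center sits at polar and azimuthal 90 degrees; with that rotation a
degree of azimuth and a degree of elevation contribute equivalently near the
screen center.

# Event classification

Saccades are classified by the velocity-threshold method with an elliptic
criterion. Velocity is computed with the 5-point difference kernel

v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt),

which is exact for linear signals and suppresses sample noise. Per axis, a
robust noise scale is estimated as sigma = sqrt(median(v^2) - median(v)^2)
and the threshold set to eta = lambda * sigma with lambda = 5 by default. A
sample is saccadic when (v_x/eta_x)^2 + (v_y/eta_y)^2 > 1; runs of at least
3 such samples become events, and runs separated by a single sample merge.
Run on a sustained-fixation segment alone, the identical classifier
recovers microsaccades.

Two delimitation details matter in practice:

* **Boundary refinement.** The threshold crossing necessarily lags the true
  movement onset — a velocity pulse must rise through the noise band before
  it can cross lambda * sigma. After detection, each event's onset is
  therefore walked backward (and its offset forward) to the first sample
  whose criterion value falls below a lower delimitation threshold
  (`onset_lambda = 3` by default). On simulated microsaccades at 500 Hz
  this reduces the mean onset error from about 4.5 ms to below 3 ms.
  Near-threshold events (0.1–0.2 degrees against 0.05-degree fixational
  noise) still carry individual onset errors of up to ~8 ms; that delay is
  a property of threshold crossing, not of the implementation.
* **A noise floor** (`sigma_floor`) keeps the threshold positive on
  noiseless synthetic input, where the median estimator would collapse to
  zero and flag everything.

Blinks are detected by the modality each tracker exposes: missing-pupil
runs (gap detector) for devices that drop the pupil sample, and a smoothed
differential filter on the confidence channel for devices that signal
blinks by confidence collapse. For the confidence detector, among
consecutive onset candidates only the last is kept, and an onset without a
subsequent offset is discarded — a blink may only begin if it also ends.
The smoothing window (0.15 s) and the derivative threshold (0.5 of the
absolute range) are declared defaults of this implementation, recorded in
the configuration, not reproductions of any proprietary constant.

Fixations are the labelled complement: blink events are padded by
±100 ms, padded-blink samples win over saccade claims (without a pupil the
reported position is untrustworthy), and every remaining sample is a
fixation sample. Fixation events shorter than 50 ms are removed and their
samples labelled `none`. Every retained sample ends up with exactly one
label — a partition that the test suite asserts.

Irregularly sampled fused streams are resampled to a constant 240 Hz with
piecewise cubic Hermite interpolation (PCHIP) before classification. PCHIP
is shape-preserving: it cannot overshoot the data, so it does not
manufacture spurious velocity peaks the way an unconstrained cubic spline
can. Gaps longer than 50 ms (closed eyes) are never interpolated across;
segments are resampled independently. Classified event timings should be
interpreted on, and mapped back to, the original samples.

# Data quality metrics

Spatial accuracy is the angular offset between the instructed target and
the gaze the participant confirmed: by default the mean position of the
last fixation ongoing at (or ending just before) the confirming key press;
for the head-roll task, where a stable fixation often persists through the
movement, the winsorized mean sample position in the 0.5 s before the press
is used instead.

Precision has two standard readings, both computed per fixation event:
theta_RMS, the root-mean-square of consecutive-sample angular distances
(sample-to-sample noise), and theta_sd, the RMS angular distance to the
mean position (spread). For a two-point alternating stream theta_RMS
equals twice theta_sd; for white per-axis noise of SD sigma, theta_RMS is
approximately 2 sigma.

All group statistics use the 20% winsorized mean (per tail), aggregated in
a fixed order: targets (or trials) within block, blocks within subject,
subjects into the group value — the reported dispersion is that of subject
means, not the mean of within-subject dispersions. Group confidence
intervals use the Tukey–McLaughlin winsorized-t form with effective degrees
of freedom n − 2k − 1, with a seeded percentile bootstrap (10,000
resamples) as an option; the pupil summaries use the bootstrap by default.
Winsorizing 20% per tail follows the robust-statistics literature the
method originates from; the main alternative reading (20% total) would be
gamma = 0.1 per tail and is one argument away.

Calibration decay is summarized by paired winsorized differences of
subject-level accuracy between each later timepoint and the
post-calibration baseline, with winsorized-t intervals. A robust linear
mixed model is the natural inferential upgrade when per-trial data and
crossed random effects are of interest; it is deliberately out of scope
here, and the decay output is labelled as paired differences.

# The pursuit hinge model

Step-ramp pursuit trials are rotated so axis 1 lies along the target's
motion. Samples enter the fit from motion onset up to the first saccade
exceeding 1 degree (a catch-up saccade) or 600 ms, whichever comes first;
blink samples are excluded. The model is a restricted two-piece linear
regression

mu(t) = alpha + w(t) * beta * (t - tau),  w(t) = 1 / (1 + exp(-(t - tau)/k)),

with the first piece constrained to slope zero. Priors: alpha ~ Normal(0,
1 deg); tau ~ Normal(0.185 s, 0.300 s); beta ~ Normal(0, 20 deg/s)
truncated at zero (the eye is not allowed to "pursue" opposite to the
target — with strongly contrary data the posterior instead lets tau drift
beyond the fitted window); sigma ~ Normal(0, 5 deg) truncated at zero. The
logistic weight makes the likelihood differentiable at the hinge; its scale
k = 10 ms is not a scientific parameter — fits with k = 1 ms agree in tau
within 5 ms on clean data — and it is configuration-exposed and recorded.

Posterior inference uses Gibbs/Metropolis sampling (JAGS) with 4 chains of
1,000 retained draws after 500 adaptation and 500 burn-in iterations,
fully determined by the seed; fits with any split-chain R-hat at or above
1.01 are flagged and should be excluded from aggregates. A fast
MAP-plus-Laplace approximation (posterior mode in an unconstrained
parameterization, Gaussian curvature draws) is available for interactive
work; on clean trials the two agree to well within the posterior spread.
Per-trial posterior means of tau and beta feed the winsorized hierarchy
trials → blocks → subjects.

Negative tau draws are permitted (the prior is not truncated); a posterior
mean below zero flags an uninterpretable trial rather than being clipped.
Catch-up saccades are counted over the half-open target-motion window with
no attempt to separate the initial reaction saccade — a known ambiguity of
the design, absorbed by the robust aggregation.

# Pupillometry

Pupil axes are converted to area as A = (1/4) pi l1 l2. Applied to full
axes (diameters) this is the exact ellipse area. Note a units ambiguity a
careful reader will meet in the field: if l1, l2 are semi-axes the correct
area is pi l1 l2, so the 1/4-factor form silently assumes full axes. The
package applies the formula as written and leaves the axis convention of
the source device to the data dictionary; since all downstream statistics
are baseline-normalized ratios, a constant factor cancels.

Each luminance trial is normalized by the median pupil area over the 1 s
window before the bright-stimulus onset (the median resists blink
artifacts that survive padding; the window length is configuration-exposed
since baselines shorter than the pre-stimulus black period are sometimes
preferable). Normalization is exactly scale-invariant, so device units
never matter. Responses are summarized as the mean normalized area 2–3 s
after the luminance change, winsorized blocks → subjects → group with
bootstrap intervals.

# The synthetic dual-tracker simulator

The simulator exists to give every stage a ground truth. One latent eye
path drives two tracker front-ends:

* **Tracker A** samples at an exactly constant rate (500 Hz default) with
  small white measurement jitter (0.01 deg SD default) and renders blinks
  as missing pupil samples with held gaze position.
* **Tracker B** is assembled from two per-eye camera clocks at 120 Hz whose
  relative phase is random at startup. In `fusion = "average"` (default)
  successive alternating camera samples are averaged in both time and
  position, so the stream reports a perfectly constant 240 Hz regardless of
  the true phase — and acquires a step-like position artifact; in
  `"interleave"` the true camera timestamps are kept and inter-sample
  intervals alternate between phase/f and (1 − phase)/f. Tracker B runs on
  its own clock (slope offset plus a 10 ms acquisition delay) so that the
  synchronization stage has something real to do, carries larger
  measurement jitter (0.06 deg SD default), and renders blinks as a
  confidence collapse below 0.1 with a downward lid-closure ramp in y.

Saccades and microsaccades follow a raised-cosine velocity profile —
symmetric, single-peaked and bandwidth-limited — with duration given by the
linear main sequence D = 21 ms + 2.2 ms/deg * amplitude, values in the
middle of the published range for human saccades. Microsaccade and blink
onsets are Poisson processes (counts exactly Poisson; overlapping onsets
are re-drawn); microsaccade directions are uniform with mean reversion once
the accumulated displacement exceeds the amplitude range, keeping simulated
fixation stationary.

Fixational noise is an Ornstein–Uhlenbeck (band-limited) process with
stationary SD `fixation_noise_sd` (default 0.2 deg, matching reported
fixation-spread magnitudes) and correlation time 0.1 s, the timescale of
slow fixational drift. The band-limited choice, rather than white position
noise at the sampling rate, is deliberate: oculomotor position is
continuous, so the velocity content of fixational noise must not grow with
the tracker's sampling rate. White noise of the same SD added per sample at
500 Hz would put ~8 deg/s of noise into the velocity channel and make
sub-0.45-degree microsaccades undetectable in principle at lambda = 5;
under the OU model the same positional SD leaves small microsaccades
recoverable, which is what real trackers show. Measurement jitter — which
*is* white — is a separate per-tracker knob.

The pupil relaxes exponentially (time constant 0.5 s) toward a
luminance-dependent steady state interpolated on log-luminance; only
normalized responses are meaningful, so the steady-state table is in
arbitrary device units. Calibration decay can be emulated through a linear
position-drift knob (`drift_rate`, deg/s, fixed random direction); no
published quantitative slippage model exists, so its magnitude is
user-set.

What the simulator does **not** emulate: pupil-detection image processing,
gaze-position-dependent pupil foreshortening, nonlinear calibration warps
between trackers, head movement, and the heavy-tailed artifact bursts some
mobile trackers produce. Recovery results on synthetic data therefore
bound what the pipeline can do under clean assumptions; they do not certify
performance on any particular device.

# Problem sizes and numerical choices

The recovery studies shipped with the package use six 20 s fixation blocks
with 30 injected microsaccades each for detection recall, and 100 pursuit
trials of 0.6 s at 500 Hz for hinge-model recovery — sizes at which the
binomial and posterior uncertainties of the reported quantities are a few
percent, chosen as the package's standard desk-scale benchmark.

Ties and degenerate inputs: event intervals are half-open [onset, offset),
so abutting events share no sample; cross-tracker event matching is greedy
one-to-one by largest temporal overlap (containment counts as overlap);
winsorization with gamma * n < 1 is the identity; clock fits require at
least two shared triggers and warn above 5 ms residual SD; a Theil–Sen
slope is available for glitched trigger logs.

# Known limitations

* The confidence-channel blink detector's constants are declared defaults,
  not reproductions of any vendor's pipeline; on real glasses data they
  may need retuning.
* Saccade amplitude is the angular distance between the event's endpoint
  positions; peak-to-peak displacement can be larger for curved saccades.
* The decay summary is a paired-difference analysis, not a mixed model; it
  does not partition variance across blocks and subjects.
* Group pursuit summaries assume per-trial fits are exchangeable within a
  block; systematic within-block learning would be invisible.
* The per-axis spherical conversion treats azimuth and elevation
  independently; at the extreme grid corners (~20 degrees) the
  small-angle coupling it ignores is at the arcminute level.
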