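# gazeqc

Eye-tracker data-quality analysis for multi-task test batteries, with a
synthetic dual-tracker gaze simulator providing ground truth for every
analysis stage.

## The problem

Manufacturer-quoted accuracy and precision numbers do not describe how an
eye-tracker behaves over a session: calibration decays, blinks and
microsaccades are classified with device-specific reliability, smooth
pursuit and pupillometry stress different parts of the pipeline. A standard
way to characterize a device is a battery of short tasks — fixation grids,
step-ramp pursuit, free viewing, sustained fixation (microsaccades),
cued blinks, luminance steps, head movements — recorded simultaneously on
the device under test and a reference tracker, then reduced to robust
group statistics. `gazeqc` implements that reduction end to end, for anyone
evaluating a tracker, reprocessing a published battery, or validating an
event-classification change against ground truth.

## What is inside

* **Synchronization and cleaning** — OLS (or Theil–Sen) clock maps from
  shared trigger messages, `t' = slope * t + offset - constant_delay`
  (10 ms default delay for fused-camera glasses); exclusion of samples with
  no pupil, off-screen gaze, or corruption flags; shape-preserving (PCHIP)
  resampling to a constant rate that never interpolates across blinks.
* **Geometry** — per-axis pixel to spherical-degree conversion
  `beta = 2 * atan2(p * m, d)`; great-circle angular distances in a frame
  where both axes contribute equivalently; rotation into target-aligned
  coordinates.
* **Event classification** — velocity-threshold saccade detection with the
  elliptic criterion `(v_x/eta_x)^2 + (v_y/eta_y)^2 > 1`,
  `eta = lambda * sigma_median`, `lambda = 5`; the same classifier on
  fixation segments recovers microsaccades; blink detection by missing
  pupil (gap) or by confidence collapse (smoothed differential filter,
  keep-last-onset rule); fixation labelling as the complement with ±100 ms
  blink padding and a 50 ms minimum duration; greedy one-to-one
  cross-tracker event matching by temporal overlap.
* **Quality metrics** — spatial accuracy against the confirmed fixation
  (last fixation before key press, or a 0.5 s pre-press window for the
  head-roll task); precision as theta_RMS (consecutive-sample distances)
  and theta_sd (spread around the mean); 20% winsorized means with
  Tukey–McLaughlin or bootstrap intervals, aggregated targets → blocks →
  subjects; paired winsorized decay contrasts; free-viewing statistics and
  3-degree Gaussian fixation density maps.
* **Pursuit hinge model** — Bayesian restricted two-piece regression of
  gaze along the target direction: flat at alpha until onset tau, then
  slope beta ≥ 0, with priors alpha ~ N(0, 1°), tau ~ N(0.185 s, 0.300 s),
  beta ~ half-N(0, 20°/s), sigma ~ half-N(0, 5°) and a logistic hinge
  transfer; seeded MCMC (JAGS, 4 × 1000 draws) or MAP + Laplace;
  `pursuit_fit` objects with `print`, `summary`, `coef`, `predict`,
  `residuals`, `plot` methods; catch-up saccade counting.
* **Pupillometry** — ellipse area `A = (1/4) pi l1 l2`, median-baseline
  normalization (exactly scale-invariant), per-luminance winsorized
  summaries over the 2–3 s window.
* **Battery schedules** — 7 × 7 grid over ±18.2° × ±7.7° and its 13-point
  calibration subset; entropy-maximizing constrained randomization
  (17 × 1° amplitude bins, 10 × 36° angle bins, 55:45 weighting); pupil
  luminance sequences; step-ramp pursuit schedules (5 speeds × 24
  directions); head-task target sets.
* **Simulator** — one latent gaze path sampled by two tracker front-ends:
  exact constant-rate monocular sampling, and a dual-camera stream with
  random inter-camera phase and pair-averaging fusion (constant reported
  240 Hz, step artifact); OU fixational noise, raised-cosine main-sequence
  saccades, Poisson microsaccades/blinks rendered per tracker modality,
  luminance-driven pupil, separate tracker clocks; full ground-truth event
  log.

## Worked example

Simulate a 20 s fixation block with 30 injected microsaccades
(0.1–1°, 0.05° fixational noise), classify the 500 Hz stream, and match
against ground truth:

```r
library(gazeqc)

cfg <- simulation_config(seed = 42, fixation_noise_sd = 0.05,
                         microsaccade_count = 30, blink_rate = 0)
sched <- data.frame(type = "fixation", duration_s = 20, x_deg = 0, y_deg = 0)
ses <- simulate_session(cfg, sched)

truth <- subset(ses$ground_truth$events, type == "microsaccade")
det <- detect_saccades(ses$stream_a, detector_config())
m <- match_events(truth, det)
sprintf("injected: %d   detected: %d   matched: %d (recall %.2f)",
        nrow(truth), nrow(det), m$n_hit, m$n_hit / nrow(truth))
#> "injected: 30   detected: 28   matched: 28 (recall 0.93)"
sprintf("mean onset error: %.1f ms",
        1000 * mean(abs(det$onset[m$pairs$b] - truth$onset[m$pairs$a])))
#> "mean onset error: 2.3 ms"
```

The two misses are 0.11° and 0.14° events whose raised-cosine velocity peaks sit
below the lambda = 5 threshold implied by the injected noise — small
microsaccades near the noise floor are the events a velocity-threshold
classifier gives up first.

Fit the pursuit hinge model to one synthetic step-ramp trial (true onset
0.200 s, true velocity 18°/s, 0.3° noise):

```r
trial <- simulate_pursuit_trial(tau = 0.2, beta = 18, sigma = 0.3, seed = 1)
fit <- fit_hinge(trial, pursuit_config(seed = 1))
fit
#> Bayesian hinge pursuit fit (mcmc)
#>   onset tau: 0.203 s   velocity beta: 18.09 deg/s
#>   intercept alpha: 0.042 deg   noise sigma: 0.292 deg
#>   flagged: max R-hat 1.015 >= 1.01 (inspect before aggregating)
```

The posterior mean onset lands 3 ms from truth and the velocity within
0.1°/s; the R-hat flag notes that chains mixed slightly above the strict
1.01 bound at the default draw count (the posterior means are stable —
doubling `draws` brings R-hat under 1.01).

Robust aggregation, the way every group statistic in the battery is formed:

```r
w <- winsorized_mean(c(0.41, 0.52, 0.47, 0.44, 2.9), gamma = 0.2)
sprintf("winsorized accuracy: %.3f deg (95%% CI %.3f-%.3f)",
        w$mean, w$ci[1], w$ci[2])
#> "winsorized accuracy: 0.478 deg (95% CI 0.349-0.607)"
```

The 2.9° outlier (a mislabelled fixation, say) is replaced by the nearest
retained order statistic instead of dragging the mean to 0.95°.

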