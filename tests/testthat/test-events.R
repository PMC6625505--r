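test_that("velocity kernel is exact for constant and linear signals", {
  s <- make_stream(rep(1.5, 50), rep(-2, 50))
  v <- compute_velocity(s)
  expect_true(all(v$vx == 0) && all(v$vy == 0))
  t <- (0:99) / 500
  s2 <- make_stream(7 * t, -3 * t)
  v2 <- compute_velocity(s2)
  expect_equal(v2$vx, rep(7, 100), tolerance = 1e-9)
  expect_equal(v2$vy, rep(-3, 100), tolerance = 1e-9)
  expect_error(compute_velocity(make_stream(1:4 / 10, 1:4 / 10)), "at least 5")
})

test_that("velocity on a smooth trace matches a centered-difference oracle", {
  t <- (0:499) / 500
  x <- sin(2 * pi * 1.3 * t)          # max third derivative bounds the kernel error
  s <- make_stream(x, x)
  v <- compute_velocity(s)$vx
  v_true <- 2 * pi * 1.3 * cos(2 * pi * 1.3 * t)
  # kernel has O(dt^2) bias; generous bound for a 1.3 Hz sinusoid at 500 Hz
  expect_lt(max(abs(v - v_true)[5:495]), 0.01)
})

test_that("saccade detection finds nothing on pure fixation and one injected saccade exactly", {
  quiet <- make_stream(rnorm(800, 0, 1e-4), rnorm(800, 0, 1e-4))
  expect_equal(nrow(detect_saccades(quiet, detector_config())), 0)

  s <- inject_saccade(1000, at = 400, amplitude = 5, direction = 0,
                      noise_sd = 0.02, seed = 3)
  ev <- detect_saccades(s, detector_config())
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$amplitude - 5) / 5, 0.05)
  expect_equal(ev$type, "saccade")
})

test_that("detected boundaries are identical to the brute-force elliptic-criterion oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(300:1000, 1)
    s <- inject_saccade(n, at = round(n / 2), amplitude = runif(1, 0.5, 6),
                        direction = runif(1, 0, 360), noise_sd = 0.03,
                        seed = seed + 100)
    for (lam in c(3, 5, 8)) {
      cfg <- detector_config(lambda = lam)
      ev <- detect_saccades(s, cfg)
      bounds <- oracle_saccade_bounds(s$x_deg, s$y_deg, dt = 1 / 500,
                                      lambda = lam)
      expect_equal(nrow(ev), nrow(bounds))
      if (nrow(ev) > 0) {
        expect_equal(ev$onset, s$t_s[bounds[, 1]])
        expect_equal(ev$offset, s$t_s[bounds[, 2]] + 1 / 500)
      }
    }
  }
})

test_that("the number of detected saccades is non-increasing in lambda", {
  set.seed(9)
  cfgs <- lapply(c(3, 5, 8), function(l) detector_config(lambda = l))
  for (seed in 1:4) {
    x <- cumsum(rnorm(2000, 0, 0.01))
    y <- cumsum(rnorm(2000, 0, 0.01))
    s <- make_stream(x, y)
    counts <- vapply(cfgs, function(cf) nrow(detect_saccades(s, cf)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("confidence-based blink detection finds square dips and keeps the last of consecutive onsets", {
  t <- seq(0, 10, by = 1 / 240)
  conf <- rep(0.95, length(t))
  expect_equal(nrow(detect_blinks_confidence(
    sample_stream(t_s = t, x_deg = 0 * t, y_deg = 0 * t, confidence = conf))), 0)

  conf[t >= 4 & t < 4.25] <- 0.05
  s <- sample_stream(t_s = t, x_deg = 0 * t, y_deg = 0 * t, confidence = conf)
  b <- detect_blinks_confidence(s)
  expect_equal(nrow(b), 1)
  # covers the dip to within one smoothing window
  expect_lt(abs(b$onset - 4), 0.16)
  expect_lt(abs(b$offset - 4.25), 0.16)
  expect_true(b$onset <= 4 + 0.01 && b$offset >= 4.25 - 0.01)

  # two drops (onset candidates) before a single recovery: use the later one
  conf2 <- rep(1, length(t))
  conf2[t >= 3 & t < 5] <- 0.5
  conf2[t >= 5 & t < 6] <- 0.0
  conf2[t >= 6] <- 1
  s2 <- sample_stream(t_s = t, x_deg = 0 * t, y_deg = 0 * t,
                      confidence = conf2)
  b2 <- detect_blinks_confidence(s2, detector_config(
    confidence_filter_threshold = 0.3))
  expect_equal(nrow(b2), 1)
  expect_gt(b2$onset, 4.5)   # the second (later) drop, not the first
})

test_that("gap-based blink detection enumerates missing-pupil runs without merging", {
  t <- (0:999) / 250
  p <- rep(200, 1000)
  s0 <- sample_stream(t_s = t, x_deg = 0 * t, y_deg = 0 * t, pupil = p)
  expect_equal(nrow(detect_blinks_gap(s0)), 0)

  p[251:300] <- NA   # 200 ms
  s1 <- sample_stream(t_s = t, x_deg = 0 * t, y_deg = 0 * t, pupil = p)
  b1 <- detect_blinks_gap(s1)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$offset - b1$onset, 0.2)

  p[500:520] <- NA; p[522:540] <- NA   # two runs, one valid sample apart
  s2 <- sample_stream(t_s = t, x_deg = 0 * t, y_deg = 0 * t, pupil = p)
  expect_equal(nrow(detect_blinks_gap(s2)), 3)
})

test_that("fixation labelling applies blink padding and the minimum-duration rule", {
  rate <- 500
  t <- (0:1499) / rate        # 3 s
  s <- make_stream(rep(0, 1500), rep(0, 1500), rate = rate)
  blinks <- data.frame(type = "blink", onset = 1.0, offset = 1.2,
                       amplitude = NA, peak_velocity = NA, mean_x = NA,
                       mean_y = NA, n_samples = 100L)
  lab <- label_fixations(s, NULL, blinks, detector_config())
  inside_pad <- lab$stream$t_s >= 0.9 & lab$stream$t_s < 1.3
  expect_true(all(lab$stream$label[inside_pad] == "blink"))
  expect_true(all(lab$stream$label[!inside_pad] == "fixation"))

  # a 40 ms fixation islet between two blinks is removed
  blinks2 <- rbind(blinks,
                   data.frame(type = "blink", onset = 1.44, offset = 1.64,
                              amplitude = NA, peak_velocity = NA, mean_x = NA,
                              mean_y = NA, n_samples = 100L))
  lab2 <- label_fixations(s, NULL, blinks2, detector_config())
  islet <- lab2$stream$t_s >= 1.30 & lab2$stream$t_s < 1.34
  expect_true(all(lab2$stream$label[islet] == "none"))
})

test_that("one central saccade yields exactly two flanking fixations and a full label partition", {
  s <- inject_saccade(1000, at = 500, amplitude = 4, noise_sd = 0.02, seed = 5)
  sac <- detect_saccades(s, detector_config())
  lab <- label_fixations(s, sac, NULL, detector_config())
  fix <- lab$events[lab$events$type == "fixation", ]
  expect_equal(nrow(fix), 2)
  expect_lt(fix$offset[1], fix$onset[2])
  # partition: every sample carries exactly one label
  expect_true(all(lab$stream$label %in% c("fixation", "saccade", "blink", "none")))
  expect_equal(sum(table(lab$stream$label)), nrow(s))
})

test_that("event matching is greedy one-to-one by largest overlap", {
  a <- data.frame(type = "saccade", onset = 0, offset = 0.02)
  b <- data.frame(type = "saccade", onset = c(0.01, 0.015),
                  offset = c(0.03, 0.018))
  m <- match_events(a, b)
  expect_equal(m$n_hit, 1)
  expect_equal(m$pairs$b, 1)       # larger overlap (0.01 s) beats containment
  expect_equal(m$unmatched_b, 2)

  ident <- data.frame(onset = c(0, 1), offset = c(0.5, 1.5))
  expect_equal(match_events(ident, ident)$n_hit, 2)
  disj <- data.frame(onset = 3, offset = 3.5)
  expect_equal(match_events(ident, disj)$n_hit, 0)
})
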