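test_that("winsorized mean matches hand computation and degenerate cases", {
  w <- winsorized_mean(c(1, 2, 3, 4, 100), gamma = 0.2)
  expect_equal(w$mean, 3.0)          # winsorized vector is 2,2,3,4,4
  wc <- winsorized_mean(rep(7, 12))
  expect_equal(wc$mean, 7)
  expect_equal(diff(wc$ci), 0)
  x <- rnorm(20)
  expect_equal(winsorized_mean(x, gamma = 0)$mean, mean(x))
  expect_error(winsorized_mean(x, gamma = 0.5), "gamma")
})

test_that("winsorized mean equals the sort-and-replace oracle and is permutation-invariant", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(2:60, 1)
    x <- rcauchy(n)          # heavy tails stress the winsorization
    g <- runif(1, 0, 0.49)
    m <- winsorized_mean(x, g)$mean
    expect_equal(m, oracle_winsorized_mean(x, g))
    expect_equal(winsorized_mean(sample(x), g)$mean, m)
    expect_true(m >= min(x) && m <= max(x))
  }
})

test_that("precision formulas agree with direct summation and each other", {
  # constant samples
  expect_equal(precision_rms(rep(1, 10), rep(2, 10)), 0)
  expect_equal(precision_sd(rep(1, 10), rep(2, 10)), 0)
  # alternation between two points delta apart: RMS = delta, SD = delta/2
  x <- rep(c(0, 0.3), 20); y <- rep(0, 40)
  expect_equal(precision_rms(x, y), 0.3, tolerance = 1e-6)
  expect_equal(precision_sd(x, y), 0.15, tolerance = 1e-6)
  expect_equal(precision_rms(x, y), 2 * precision_sd(x, y), tolerance = 1e-6)
  # small-angle white noise: theta_RMS ~ 2 sigma
  set.seed(3)
  xs <- rnorm(20000, 0, 0.05); ys <- rnorm(20000, 0, 0.05)
  expect_equal(precision_rms(xs, ys), 2 * 0.05, tolerance = 0.03)
})

test_that("target accuracy selects the last fixation before the key press", {
  fx <- data.frame(type = "fixation",
                   onset = c(0.0, 0.8, 1.6), offset = c(0.7, 1.5, 2.4),
                   amplitude = 0, peak_velocity = NA,
                   mean_x = c(5, 1, 0), mean_y = c(0, 0, 0),
                   n_samples = 100L)
  tg <- data.frame(x_deg = 0, y_deg = 0, t_press = 2.0)
  acc <- target_accuracy(fx, tg)
  expect_equal(acc$offset_deg, 0)    # ongoing fixation at press is the third
  tg2 <- data.frame(x_deg = 0, y_deg = 0, t_press = 1.2)
  expect_equal(target_accuracy(fx, tg2)$offset_deg, 1)
  # single-axis arc
  tg3 <- data.frame(x_deg = 4, y_deg = 0, t_press = 0.5)
  expect_equal(target_accuracy(fx, tg3)$offset_deg, 1)  # fixation at 5 deg
})

test_that("windowed (head-roll) accuracy uses the winsorized pre-press position", {
  t <- (0:499) / 500
  s <- sample_stream(t_s = t, x_deg = rep(1, 500), y_deg = rep(0, 500),
                     pupil = 1, confidence = 1)
  s$label <- "fixation"
  tg <- data.frame(x_deg = 0, y_deg = 0, t_press = 0.9)
  acc <- target_accuracy(NULL, tg, method = "window_mean", stream = s)
  expect_equal(acc$offset_deg, 1, tolerance = 1e-9)
})

test_that("group accuracy recovers pure noise radial error on a simulated grid block", {
  # zero bias, per-axis noise SD 0.2: expected 2D radial error = 0.2*sqrt(pi/2)
  set.seed(42)
  rows <- list()
  for (subj in 1:4) for (blk in 1:3) {
    g <- make_grid()
    fx <- g$x_deg + rnorm(49, 0, 0.2)
    fy <- g$y_deg + rnorm(49, 0, 0.2)
    rows[[length(rows) + 1]] <- data.frame(
      subject = subj, block = blk,
      offset_deg = angular_distance(fx, fy, g$x_deg, g$y_deg))
  }
  df <- do.call(rbind, rows)
  res <- accuracy_summary(df)
  expect_gt(res$mean, 0.15)
  expect_lt(res$mean, 0.35)
  # permutation invariance within aggregation levels
  res2 <- accuracy_summary(df[sample(nrow(df)), ])
  expect_equal(res2$mean, res$mean)
})

test_that("recovered accuracy converges to the injected bias as noise shrinks", {
  set.seed(7)
  bias <- 0.3
  means <- vapply(c(0.4, 0.1, 0.01), function(sig) {
    g <- make_grid()
    fx <- g$x_deg + bias + rnorm(49, 0, sig)
    fy <- g$y_deg + rnorm(49, 0, sig)
    winsorized_mean(angular_distance(fx, fy, g$x_deg, g$y_deg))$mean
  }, numeric(1))
  expect_true(all(diff(abs(means - bias)) < 0))   # monotone convergence
  expect_lt(abs(means[3] - bias), 0.01)
})

test_that("decay summary is zero for identical timepoints and antisymmetric", {
  df <- expand.grid(subject = 1:6, timepoint = c("t0", "t1", "t2"))
  df$accuracy <- 0.5
  d <- decay_summary(df, baseline = "t0")
  expect_equal(d$diff, c(0, 0))
  set.seed(1)
  df$accuracy <- runif(nrow(df), 0.3, 1)
  d1 <- decay_summary(df[df$timepoint != "t2", ], baseline = "t0")
  d2 <- df[df$timepoint != "t2", ]
  d2$timepoint <- ifelse(d2$timepoint == "t0", "t1", "t0")
  d2 <- decay_summary(d2, baseline = "t0")
  expect_equal(d1$diff, -d2$diff)
})

test_that("decay summary recovers an injected accuracy drift", {
  set.seed(13)
  rows <- list()
  for (subj in 1:10) {
    base <- runif(1, 0.3, 0.6)
    rows[[length(rows) + 1]] <- data.frame(
      subject = subj, timepoint = c("t0", "t1"),
      accuracy = c(base + rnorm(1, 0, 0.05), base + 0.3 + rnorm(1, 0, 0.05)))
  }
  d <- decay_summary(do.call(rbind, rows), baseline = "t0")
  expect_true(d$ci_lo < 0.3 && d$ci_hi > 0.3)
})

test_that("free-viewing statistics exclude the first fixation", {
  ev <- data.frame(type = c(rep("fixation", 10), "saccade"),
                   onset = c(seq(0, 4.5, by = 0.5), 0.26),
                   offset = c(seq(0.25, 4.75, by = 0.5), 0.3),
                   amplitude = c(rep(0, 10), 3.2), peak_velocity = NA,
                   mean_x = 0, mean_y = 0, n_samples = 10L)
  st <- freeview_stats(ev)
  expect_equal(st$n_fixations, 9)
  expect_equal(unique(st$durations), 0.25)
  expect_equal(st$amplitudes, 3.2)
})

test_that("fixation density peaks at the fixation and conserves mass under smoothing", {
  geom <- screen_geometry()
  d1 <- fixation_density(0, 0, geom, kernel_sd = 3)
  peak <- which(d1$density == max(d1$density), arr.ind = TRUE)
  expect_lt(abs(d1$x_px[peak[1, 2]]), 15)
  expect_lt(abs(d1$y_px[peak[1, 1]]), 15)
  expect_equal(sum(d1$density), 1, tolerance = 0.01)  # boundary loss < 1%
  # two equal clusters give two equal modes
  d2 <- fixation_density(c(-8, 8), c(0, 0), geom, kernel_sd = 1)
  left <- d2$density[, d2$x_px < 0]
  right <- d2$density[, d2$x_px > 0]
  expect_equal(max(left), max(right), tolerance = 1e-6)
})
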