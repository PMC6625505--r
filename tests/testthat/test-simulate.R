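fix_sched <- function(dur = 10) data.frame(type = "fixation",
                                           duration_s = dur,
                                           x_deg = 0, y_deg = 0)

test_that("the noiseless degenerate case puts every tracker-A sample on the target", {
  cfg <- simulation_config(seed = 1, fixation_noise_sd = 0,
                           measurement_noise_a = 0, measurement_noise_b = 0,
                           microsaccade_rate = 0, blink_rate = 0)
  sched <- data.frame(type = "fixation", duration_s = 2, x_deg = 3, y_deg = -1)
  ses <- simulate_session(cfg, sched)
  expect_true(all(ses$stream_a$x_deg == 3))
  expect_true(all(ses$stream_a$y_deg == -1))
})

test_that("identical configuration and schedule give identical output", {
  cfg <- simulation_config(seed = 77)
  s1 <- simulate_session(cfg, fix_sched(5))
  s2 <- simulate_session(cfg, fix_sched(5))
  expect_identical(s1$stream_a, s2$stream_a)
  expect_identical(s1$stream_b, s2$stream_b)
  expect_identical(s1$ground_truth$events, s2$ground_truth$events)
  s3 <- simulate_session(simulation_config(seed = 78), fix_sched(5))
  expect_false(identical(s1$stream_a, s3$stream_a))
})

test_that("tracker A inter-sample intervals are exactly constant", {
  ses <- simulate_session(simulation_config(seed = 3), fix_sched(5))
  d <- diff(ses$stream_a$t_s)
  expect_lt(max(d) - min(d), 1e-12)
})

test_that("event counts follow the Poisson law over repeated seeds", {
  # exact Poisson counts by construction; pooled over 20 seeds
  n_ms <- 0; n_bl <- 0
  for (seed in 1:20) {
    cfg <- simulation_config(seed = seed, microsaccade_rate = 1.5,
                             blink_rate = 0.2, sim_rate = 500)
    gt <- simulate_session(cfg, fix_sched(10))$ground_truth$events
    n_ms <- n_ms + sum(gt$type == "microsaccade")
    n_bl <- n_bl + sum(gt$type == "blink")
  }
  lam_ms <- 20 * 1.5 * (10 - 0.1)    # rate over the usable fixation window
  lam_bl <- 20 * 0.2 * (10 - 1.0)
  expect_gte(n_ms, qpois(0.005, lam_ms))
  expect_lte(n_ms, qpois(0.995, lam_ms))
  expect_gte(n_bl, qpois(0.005, lam_bl))
  expect_lte(n_bl, qpois(0.995, lam_bl))
})

test_that("single-seed event counts fall in the Poisson band of the spec example", {
  cfg <- simulation_config(seed = 123, microsaccade_rate = 1.5,
                           blink_rate = 0, sim_rate = 500)
  gt <- simulate_session(cfg, fix_sched(60))$ground_truth$events
  n <- sum(gt$type == "microsaccade")
  expect_gte(n, qpois(0.005, 1.5 * 60))
  expect_lte(n, qpois(0.995, 1.5 * 60))
})

test_that("ground-truth events are non-overlapping within type and half-open", {
  cfg <- simulation_config(seed = 5, microsaccade_rate = 2, blink_rate = 0.3)
  gt <- simulate_session(cfg, fix_sched(20))$ground_truth$events
  for (ty in unique(gt$type)) {
    e <- gt[gt$type == ty, ]
    e <- e[order(e$onset), ]
    if (nrow(e) > 1) expect_true(all(e$onset[-1] >= e$offset[-nrow(e)]))
    expect_true(all(e$offset > e$onset))
  }
})

test_that("saccade traces close displacement and follow the main sequence", {
  tr <- make_saccade_trace(5, 0, rate = 500)
  expect_equal(tr$dx[nrow(tr)], 5.0, tolerance = 1e-12)
  expect_equal(tr$dy[nrow(tr)], 0.0, tolerance = 1e-12)
  # peak velocity grows monotonically with amplitude
  peak <- vapply(c(0.1, 0.5, 1, 2, 5, 10), function(a) {
    tr <- make_saccade_trace(a, 0, rate = 2000)
    max(diff(tr$dx) / diff(tr$t))
  }, numeric(1))
  expect_true(all(diff(peak) > 0))
  # a 0.2-degree microsaccade still spans >= 3 samples at 500 Hz
  tr02 <- make_saccade_trace(0.2, 0, rate = 500)
  expect_gte(nrow(tr02), 3)
  expect_warning(make_saccade_trace(60, 0, 500), "extent")
})

test_that("displacement bookkeeping: saccades plus drift equal the net latent displacement", {
  sched <- data.frame(type = "fixation", duration_s = c(2, 2, 2),
                      x_deg = c(0, 6, -3), y_deg = c(0, 2, 1))
  cfg <- simulation_config(seed = 8, fixation_noise_sd = 0,
                           measurement_noise_a = 0, microsaccade_rate = 1,
                           blink_rate = 0)
  ses <- simulate_session(cfg, sched)
  gt <- ses$ground_truth
  sac <- gt$events[gt$events$type %in% c("saccade", "microsaccade"), ]
  th <- sac$direction * pi / 180
  net_x <- sum(sac$amplitude * cos(th))
  net_y <- sum(sac$amplitude * sin(th))
  lp <- gt$latent_path
  expect_equal(lp$x_deg[nrow(lp)] - lp$x_deg[1], net_x, tolerance = 1e-9)
  expect_equal(lp$y_deg[nrow(lp)] - lp$y_deg[1], net_y, tolerance = 1e-9)

  # with drift the residual displacement has exactly the drift magnitude
  cfg2 <- simulation_config(seed = 8, fixation_noise_sd = 0,
                            measurement_noise_a = 0, microsaccade_rate = 1,
                            blink_rate = 0, drift_rate = 0.05)
  gt2 <- simulate_session(cfg2, sched)$ground_truth
  sac2 <- gt2$events[gt2$events$type %in% c("saccade", "microsaccade"), ]
  th2 <- sac2$direction * pi / 180
  lp2 <- gt2$latent_path
  res_x <- lp2$x_deg[nrow(lp2)] - lp2$x_deg[1] - sum(sac2$amplitude * cos(th2))
  res_y <- lp2$y_deg[nrow(lp2)] - lp2$y_deg[1] - sum(sac2$amplitude * sin(th2))
  expect_equal(sqrt(res_x^2 + res_y^2), 0.05 * 6, tolerance = 1e-6)
})

test_that("dual-camera degradation reproduces the phase-dependent interval structure", {
  t <- seq(0, 1, by = 1e-3)
  x <- sin(t); y <- cos(t)
  anti <- degrade_to_dual_camera(t, x, y, 120, phase = 0.5, mode = "interleave")
  expect_equal(unique(round(diff(anti$t_s), 12)), 1 / 240)

  inph <- degrade_to_dual_camera(t, x, y, 120, phase = 0, mode = "interleave")
  expect_true(any(diff(inph$t_s) == 0))                  # duplicated stamps
  expect_equal(sum(diff(inph$t_s) > 1e-9), length(unique(inph$t_s)) - 1)

  q <- degrade_to_dual_camera(t, x, y, 120, phase = 0.25, mode = "interleave")
  ints <- sort(unique(round(diff(q$t_s), 7)))
  expect_equal(ints, round(c(0.25 / 120, 0.75 / 120), 7))  # 2.083 and 6.25 ms

  fused <- degrade_to_dual_camera(t, x, y, 120, phase = 0.31, mode = "average")
  expect_equal(unique(round(diff(fused$t_s), 12)), 1 / 240)  # constant 240 Hz
})

test_that("schedule validation rejects empty input and warns on low rates", {
  cfg <- simulation_config(seed = 1)
  expect_error(simulate_session(cfg, fix_sched(0)), "zero duration")
  cfg_slow <- simulation_config(seed = 1, tracker_a_rate = 50)
  expect_warning(simulate_session(cfg_slow, fix_sched(1)), "bandwidth")
})

test_that("a simulated session round-trips through CSV and clock synchronization", {
  cfg <- simulation_config(seed = 10, blink_rate = 0.2)
  ses <- simulate_session(cfg, fix_sched(6))
  dir <- tempfile("session")
  write_session(ses, dir)
  a <- read_samples(file.path(dir, "stream_a.csv"))
  expect_equal(nrow(a), nrow(ses$stream_a))
  expect_equal(a$x_deg, ses$stream_a$x_deg, tolerance = 1e-9)
  trg <- read_triggers(file.path(dir, "triggers.csv"))
  map <- synchronize_clocks(trg, "t_b", "t_stim", constant_delay = 0.010)
  # the recovered mapping undoes the simulated clock: stream B times map back
  # onto the stimulus clock within a fraction of a sample
  tb <- apply_clock_map(map, ses$stream_b$t_s)
  expect_lt(max(abs(range(tb) - c(0, 6))), 0.01)
  expect_equal(map$slope, 1 / ses$ground_truth$clock_b[["slope"]],
               tolerance = 1e-6)
})

test_that("pursuit segments carry their true onset and velocity in the ground truth", {
  sched <- data.frame(type = c("fixation", "pursuit"),
                      duration_s = c(1, 1), x_deg = 0, y_deg = 0,
                      speed = c(NA, 20), direction = c(NA, 0),
                      onset_latency = c(NA, 0.25), velocity_gain = c(NA, 0.9))
  cfg <- simulation_config(seed = 2, fixation_noise_sd = 0,
                           measurement_noise_a = 0, microsaccade_rate = 0,
                           blink_rate = 0)
  ses <- simulate_session(cfg, sched)
  pp <- ses$ground_truth$pursuit_params
  expect_equal(pp$tau_star, 0.25)
  expect_equal(pp$beta_star, 18)
  # latent velocity after onset equals beta_star
  lp <- ses$ground_truth$latent_path
  sel <- lp$t > 1.3 & lp$t < 1.9
  v <- diff(lp$x_deg[sel]) / diff(lp$t[sel])
  expect_equal(mean(v), 18, tolerance = 1e-6)
})

test_that("a YAML configuration file builds the simulation configuration", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "tracker_a_rate: 250", "fixation_noise_sd: 0.1",
               "camera_phase: 0.25"), path)
  cfg <- read_simulation_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$tracker_a_rate, 250)
  expect_equal(cfg$camera_phase, 0.25)
  writeLines(c("seed: 9", "no_such_key: 1"), path)
  expect_error(read_simulation_config(path), "unknown configuration keys")
})
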