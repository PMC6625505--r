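#' Simulation configuration for the dual-tracker gaze simulator
#'
#' Defines one simulated recording: a latent eye-position path shared by two
#' trackers — tracker A sampling at an exactly constant rate (default
#' 500 Hz, monocular) and tracker B fused from two cameras (default 120 Hz
#' each) whose relative sampling phase is random at startup.
#'
#' Fixational noise is a band-limited Ornstein-Uhlenbeck process on position
#' with stationary SD \code{fixation_noise_sd} and correlation time
#' \code{noise_time_constant}; this keeps the velocity content of
#' oculomotor noise independent of the tracker's sampling rate (white
#' position noise at the sample rate would not). Per-tracker white
#' measurement jitter is separate (\code{measurement_noise_a/b}). Saccades
#' and microsaccades follow a raised-cosine velocity profile with a linear
#' main sequence for duration. Blinks are rendered per tracker modality:
#' tracker A loses the pupil, tracker B's confidence collapses with a
#' downward position artifact. The pupil relaxes exponentially toward a
#' luminance-dependent steady state.
#'
#' @param seed integer; fully determines the simulator output.
#' @param tracker_a_rate Hz, default 500.
#' @param tracker_b_camera_rate per-camera Hz, default 120 (two cameras).
#' @param camera_phase relative camera phase in [0, 1) or "random".
#' @param fusion tracker B fusion mode: "average" (pairwise averaging of
#'   alternating camera samples, constant reported rate — the step-artifact
#'   mode) or "interleave" (true camera timestamps).
#' @param fixation_noise_sd stationary SD of fixational noise, degrees.
#' @param noise_time_constant OU correlation time, seconds (default 0.1).
#' @param drift_rate slow linear position drift, deg/s (default 0), random
#'   fixed direction.
#' @param measurement_noise_a,measurement_noise_b white per-axis sample
#'   jitter SD, degrees.
#' @param microsaccade_rate events/s during fixation, default 1.5.
#' @param microsaccade_count if finite, inject exactly this many
#'   microsaccades (spread uniformly over fixation time) instead of a
#'   Poisson-count process; default NA (Poisson with
#'   \code{microsaccade_rate}). Used by recovery studies that condition on
#'   the event count.
#' @param microsaccade_amp_range degrees, default c(0.1, 1).
#' @param blink_rate events/s, default 0.1.
#' @param blink_duration_range seconds, default c(0.1, 0.3).
#' @param main_sequence list(slope_ms_per_deg, intercept_ms) for saccade
#'   duration, default 2.2 ms/deg + 21 ms.
#' @param pursuit_latency_mean,pursuit_latency_sd true pursuit onset latency
#'   distribution, seconds.
#' @param pursuit_gain latent tracking velocity as a fraction of target
#'   speed.
#' @param pupil_model list(luminance, area, tau_s): steady-state areas (device
#'   units) at the given luminances (cd/m2, log-interpolated) and the
#'   first-order time constant.
#' @param sim_rate internal latent-path rate, Hz (default 1000).
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1L,
                              tracker_a_rate = 500,
                              tracker_b_camera_rate = 120,
                              camera_phase = "random",
                              fusion = c("average", "interleave"),
                              fixation_noise_sd = 0.2,
                              noise_time_constant = 0.1,
                              drift_rate = 0,
                              measurement_noise_a = 0.01,
                              measurement_noise_b = 0.06,
                              microsaccade_rate = 1.5,
                              microsaccade_count = NA_integer_,
                              microsaccade_amp_range = c(0.1, 1),
                              blink_rate = 0.1,
                              blink_duration_range = c(0.1, 0.3),
                              main_sequence = list(slope_ms_per_deg = 2.2,
                                                   intercept_ms = 21),
                              pursuit_latency_mean = 0.22,
                              pursuit_latency_sd = 0.03,
                              pursuit_gain = 0.85,
                              pupil_model = list(
                                luminance = c(0.5, 12.6, 47.8, 113.7, 226.0),
                                area = c(1400, 1000, 850, 700, 600),
                                tau_s = 0.5),
                              sim_rate = 1000) {
  fusion <- match.arg(fusion)
  stopifnot(tracker_a_rate > 0, tracker_b_camera_rate > 0, sim_rate > 0,
            microsaccade_rate >= 0, blink_rate >= 0,
            fixation_noise_sd >= 0)
  if (!identical(camera_phase, "random")) {
    stopifnot(is.numeric(camera_phase), camera_phase >= 0, camera_phase < 1)
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Raised-cosine saccade displacement segment
#'
#' Positional trace of one saccade of the given amplitude and direction: the
#' velocity profile is a single-peaked symmetric raised cosine, the duration
#' follows the linear main sequence duration = intercept + slope * amplitude,
#' and the net displacement equals the amplitude along the direction.
#'
#' @param amplitude degrees (> 0).
#' @param direction degrees, 0 = +x.
#' @param rate sampling rate of the returned trace, Hz.
#' @param main_sequence list(slope_ms_per_deg, intercept_ms).
#' @return data frame \code{t} (s, from saccade onset), \code{dx, dy}
#'   (displacement from onset position, deg); last row reaches the full
#'   amplitude.
#' @export
make_saccade_trace <- function(amplitude, direction, rate,
                               main_sequence = list(slope_ms_per_deg = 2.2,
                                                    intercept_ms = 21)) {
  stopifnot(amplitude > 0)
  if (amplitude > 40) warning("amplitude exceeds typical screen extent")
  D <- (main_sequence$intercept_ms +
          main_sequence$slope_ms_per_deg * amplitude) / 1000
  t <- seq(0, D, by = 1 / rate)
  if (t[length(t)] < D) t <- c(t, D)
  ## displacement integral of v(t) = (A/D) * (1 - cos(2 pi t / D))
  s <- amplitude * (t / D - sin(2 * pi * t / D) / (2 * pi))
  th <- direction * pi / 180
  data.frame(t = t, dx = s * cos(th), dy = s * sin(th))
}

## saccade displacement evaluated at arbitrary times since onset
.saccade_profile <- function(t_rel, amplitude, duration) {
  u <- pmin(pmax(t_rel / duration, 0), 1)
  amplitude * (u - sin(2 * pi * u) / (2 * pi))
}

#' Degrade a latent gaze segment to a dual-camera fused stream
#'
#' Emulates a binocular tracker built from two cameras with equal rate but
#' arbitrary relative phase. Camera 1 samples at k/f, camera 2 at
#' (k + phase)/f. With \code{mode = "interleave"} the merged stream keeps
#' the true camera timestamps, so inter-sample intervals alternate between
#' phase/f and (1 - phase)/f. With \code{mode = "average"} each output
#' sample is the average (in time and position) of successive alternating
#' camera samples, giving a constant reported interval of 1/(2f) regardless
#' of phase — and a step-like position artifact.
#'
#' @param t,x,y latent gaze trace (dense), degrees.
#' @param camera_rate per-camera rate f, Hz.
#' @param phase relative phase in [0, 1).
#' @param mode "interleave" or "average".
#' @return data frame \code{t_s, x_deg, y_deg} plus \code{camera} (1, 2, or
#'   0 for fused averages).
#' @export
degrade_to_dual_camera <- function(t, x, y, camera_rate, phase = 0.5,
                                   mode = c("interleave", "average")) {
  mode <- match.arg(mode)
  stopifnot(camera_rate > 0, phase >= 0, phase < 1)
  f <- camera_rate
  t0 <- t[1]; t1 <- t[length(t)]
  t_c1 <- seq(t0, t1, by = 1 / f)
  t_c2 <- seq(t0 + phase / f, t1, by = 1 / f)
  cam_t <- c(t_c1, t_c2)
  cam_id <- c(rep(1L, length(t_c1)), rep(2L, length(t_c2)))
  o <- order(cam_t)
  cam_t <- cam_t[o]; cam_id <- cam_id[o]
  cam_x <- stats::approx(t, x, cam_t, rule = 2)$y
  cam_y <- stats::approx(t, y, cam_t, rule = 2)$y
  if (mode == "interleave") {
    return(data.frame(t_s = cam_t, x_deg = cam_x, y_deg = cam_y,
                      camera = cam_id))
  }
  n <- length(cam_t)
  if (n < 2) stop("segment too short for fusion")
  data.frame(t_s = (cam_t[-n] + cam_t[-1]) / 2,
             x_deg = (cam_x[-n] + cam_x[-1]) / 2,
             y_deg = (cam_y[-n] + cam_y[-1]) / 2,
             camera = 0L)
}

#' Simulate a hinge pursuit trial directly
#'
#' Generates gaze position along the target direction under the exact hinge
#' model: flat at \code{alpha} until the true onset \code{tau}, then linear
#' with slope \code{beta}, plus white Gaussian noise — the ground-truth
#' generator for pursuit-model recovery studies.
#'
#' @param tau true onset, s. @param beta true velocity, deg/s.
#' @param alpha pre-onset position, deg. @param sigma noise SD, deg.
#' @param rate sampling rate, Hz. @param duration trial length, s.
#' @param seed integer seed.
#' @return a \code{pursuit_trial} (see \code{\link{prepare_pursuit_trial}}).
#' @export
simulate_pursuit_trial <- function(tau, beta, alpha = 0, sigma = 0.3,
                                   rate = 500, duration = 0.6, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t <- seq(0, duration, by = 1 / rate)
  mu <- alpha + pmax(0, t - tau) * beta
  structure(list(t = t, pos_along = mu + stats::rnorm(length(t), 0, sigma),
                 pos_ortho = stats::rnorm(length(t), 0, sigma),
                 target_speed = beta, direction = 0,
                 restriction_end = duration, usable = TRUE,
                 truth = list(tau = tau, beta = beta, alpha = alpha,
                              sigma = sigma)),
            class = "pursuit_trial")
}

## Poisson event times with non-overlap enforced by onset resampling
## (the count stays exactly Poisson)
.poisson_events <- function(rate, t0, t1, dur_fn, max_try = 50, count = NA) {
  n <- if (is.finite(count)) as.integer(count)
  else stats::rpois(1, rate * (t1 - t0))
  if (n == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  onset <- sort(stats::runif(n, t0, t1))
  dur <- dur_fn(n)
  for (tries in seq_len(max_try)) {
    off <- onset + dur
    bad <- c(FALSE, onset[-1] < off[-n]) | off > t1
    if (!any(bad)) break
    onset[bad] <- stats::runif(sum(bad), t0, t1)
    o <- order(onset)
    onset <- onset[o]; dur <- dur[o]
  }
  keep <- c(TRUE, onset[-1] >= (onset + dur)[-n]) & onset + dur <= t1
  data.frame(onset = onset[keep], offset = (onset + dur)[keep])
}

#' Simulate one dual-tracker recording session
#'
#' Builds a dense latent eye path from a task schedule (fixation targets,
#' step-ramp pursuit segments, luminance levels), injecting main-sequence
#' saccades at target jumps, Poisson microsaccades during fixation, Poisson
#' blinks, band-limited fixational noise and optional linear drift; then
#' samples it with the two tracker front-ends and returns both streams, a
#' trigger log and the full ground truth. Identical (config, schedule) give
#' byte-identical output.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param schedule data frame of task segments with columns \code{type}
#'   ("fixation" or "pursuit"), \code{duration_s}, \code{x_deg, y_deg}
#'   (fixation target / pursuit center), and for pursuit segments
#'   \code{speed}, \code{direction} (deg/s, deg); optional \code{luminance}
#'   (cd/m2), \code{onset_latency} and \code{velocity_gain} overrides.
#' @return list with \code{stream_a}, \code{stream_b}
#'   (\code{sample_stream}s), \code{triggers} (msg, t_stim, t_a, t_b) and
#'   \code{ground_truth} (list: \code{events}, \code{latent_path},
#'   \code{pursuit_params}, \code{pupil_trace}, \code{config}).
#' @export
simulate_session <- function(config, schedule) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(schedule) == 0 || sum(schedule$duration_s) <= 0)
    stop("schedule has zero duration")
  if (config$tracker_a_rate < 100)
    warning("tracker A rate below twice the saccade bandwidth")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  duration <- sum(schedule$duration_s)
  seg_start <- cumsum(c(0, schedule$duration_s))[seq_len(nrow(schedule))]
  dt <- 1 / config$sim_rate
  t <- seq(0, duration, by = dt)
  n <- length(t)
  ms <- config$main_sequence
  sacc_dur <- function(a) (ms$intercept_ms + ms$slope_ms_per_deg * a) / 1000

  events <- list()
  pursuit_params <- list()
  x <- numeric(n); y <- numeric(n)

  ## --- microsaccades are drawn per fixation segment first; their
  ## accumulated displacement is corrected by the next targeting saccade
  ## (saccade targeting is absolute: the eye jumps to the target from
  ## wherever fixational wander left it)
  fix_segs <- which(schedule$type == "fixation")
  seg_counts <- rep(NA_integer_, nrow(schedule))
  if (is.finite(config$microsaccade_count) && length(fix_segs) > 0) {
    w <- schedule$duration_s[fix_segs]
    seg_counts[fix_segs] <- as.integer(
      stats::rmultinom(1, config$microsaccade_count, w / sum(w)))
  }
  seg_msacc <- vector("list", nrow(schedule))
  if (config$microsaccade_rate > 0 || is.finite(config$microsaccade_count)) {
    for (s in fix_segs) {
      t0 <- seg_start[s]; t1 <- t0 + schedule$duration_s[s]
      amp_draw <- function(k) stats::runif(k, config$microsaccade_amp_range[1],
                                           config$microsaccade_amp_range[2])
      ## leave room for the targeting saccade at segment start
      lead <- max(0.05, sacc_dur(40) + 0.01)
      ev <- .poisson_events(config$microsaccade_rate, t0 + lead, t1 - 0.05,
                            function(k) sacc_dur(amp_draw(k)),
                            count = seg_counts[s])
      if (nrow(ev) == 0) next
      ## re-derive amplitude from the stored duration (same main sequence)
      amp <- ((ev$offset - ev$onset) * 1000 - ms$intercept_ms) /
        ms$slope_ms_per_deg
      ## direction: uniform, but mean-reverting once wander exceeds the
      ## largest single microsaccade
      disp_x <- 0; disp_y <- 0
      dirn <- numeric(nrow(ev))
      for (i in seq_len(nrow(ev))) {
        if (sqrt(disp_x^2 + disp_y^2) > max(config$microsaccade_amp_range)) {
          dirn[i] <- atan2(-disp_y, -disp_x) * 180 / pi +
            stats::runif(1, -30, 30)
        } else dirn[i] <- stats::runif(1, 0, 360)
        disp_x <- disp_x + amp[i] * cos(dirn[i] * pi / 180)
        disp_y <- disp_y + amp[i] * sin(dirn[i] * pi / 180)
      }
      seg_msacc[[s]] <- data.frame(onset = ev$onset, offset = ev$offset,
                                   amplitude = amp, direction = dirn)
    }
  }

  ## --- base path: targeting saccades, fixational wander, pursuit ramps
  cur_x <- schedule$x_deg[1]; cur_y <- schedule$y_deg[1]
  for (s in seq_len(nrow(schedule))) {
    t0 <- seg_start[s]; t1 <- t0 + schedule$duration_s[s]
    idx <- which(t >= t0 & t < t1 + dt / 2)
    tx <- schedule$x_deg[s]; ty <- schedule$y_deg[s]
    ## targeting saccade from the current (possibly wandered) position
    amp <- sqrt((tx - cur_x)^2 + (ty - cur_y)^2)
    if (amp > 1e-9) {
      D <- sacc_dur(amp)
      dirn <- atan2(ty - cur_y, tx - cur_x) * 180 / pi
      prog <- .saccade_profile(t[idx] - t0, amp, D) / amp
      x[idx] <- cur_x + (tx - cur_x) * prog
      y[idx] <- cur_y + (ty - cur_y) * prog
      events[[length(events) + 1]] <-
        data.frame(type = "saccade", onset = t0, offset = t0 + D,
                   amplitude = amp, direction = dirn)
    } else {
      x[idx] <- tx; y[idx] <- ty
    }
    cur_x <- tx; cur_y <- ty
    if (schedule$type[s] == "fixation") {
      ## superimpose this segment's microsaccades (displacement persists to
      ## the segment end, where the next targeting saccade corrects it)
      msc <- seg_msacc[[s]]
      for (i in seq_len(NROW(msc))) {
        D_i <- msc$offset[i] - msc$onset[i]
        th <- msc$direction[i] * pi / 180
        rel <- t[idx] - msc$onset[i]
        prog <- .saccade_profile(pmax(rel, 0), msc$amplitude[i], D_i)
        x[idx] <- x[idx] + prog * cos(th)
        y[idx] <- y[idx] + prog * sin(th)
        cur_x <- cur_x + msc$amplitude[i] * cos(th)
        cur_y <- cur_y + msc$amplitude[i] * sin(th)
        events[[length(events) + 1]] <-
          data.frame(type = "microsaccade", onset = msc$onset[i],
                     offset = msc$offset[i], amplitude = msc$amplitude[i],
                     direction = msc$direction[i])
      }
    } else {  # pursuit step-ramp on top of the segment center
      speed <- schedule$speed[s]
      dirn <- schedule$direction[s]
      gain <- if (!is.null(schedule$velocity_gain) &&
                  is.finite(schedule$velocity_gain[s]))
        schedule$velocity_gain[s] else config$pursuit_gain
      lat <- if (!is.null(schedule$onset_latency) &&
                 is.finite(schedule$onset_latency[s]))
        schedule$onset_latency[s]
      else stats::rnorm(1, config$pursuit_latency_mean,
                        config$pursuit_latency_sd)
      th <- dirn * pi / 180
      adv <- pmax(0, t[idx] - t0 - lat) * gain * speed
      x[idx] <- x[idx] + adv * cos(th)
      y[idx] <- y[idx] + adv * sin(th)
      pursuit_params[[length(pursuit_params) + 1]] <-
        data.frame(segment = s, motion_onset = t0, tau_star = lat,
                   beta_star = gain * speed, speed = speed,
                   direction = dirn)
      adv_end <- max(0, t1 - t0 - lat) * gain * speed
      cur_x <- cur_x + adv_end * cos(th)
      cur_y <- cur_y + adv_end * sin(th)
    }
  }

  ## --- fixational noise (OU) and linear drift
  if (config$fixation_noise_sd > 0) {
    a <- exp(-dt / config$noise_time_constant)
    innov_sd <- config$fixation_noise_sd * sqrt(1 - a^2)
    ou <- function() {
      e <- stats::rnorm(n, 0, innov_sd)
      e[1] <- stats::rnorm(1, 0, config$fixation_noise_sd)
      stats::filter(e, a, method = "recursive")
    }
    x <- x + as.numeric(ou())
    y <- y + as.numeric(ou())
  }
  if (config$drift_rate > 0) {
    drift_dir <- stats::runif(1, 0, 2 * pi)
    x <- x + config$drift_rate * t * cos(drift_dir)
    y <- y + config$drift_rate * t * sin(drift_dir)
  }

  ## --- blinks
  blinks <- data.frame(onset = numeric(0), offset = numeric(0))
  if (config$blink_rate > 0) {
    blinks <- .poisson_events(config$blink_rate, 0.5, duration - 0.5,
                              function(k) stats::runif(k,
                                config$blink_duration_range[1],
                                config$blink_duration_range[2]))
    for (i in seq_len(nrow(blinks)))
      events[[length(events) + 1]] <-
        data.frame(type = "blink", onset = blinks$onset[i],
                   offset = blinks$offset[i], amplitude = NA_real_,
                   direction = NA_real_)
  }

  ## --- latent pupil
  lum <- if (!is.null(schedule$luminance)) schedule$luminance
  else rep(52, nrow(schedule))
  lum[!is.finite(lum)] <- 52
  pm <- config$pupil_model
  a_ss_fun <- stats::approxfun(log(pm$luminance), pm$area, rule = 2)
  a_ss <- numeric(n)
  for (s in seq_len(nrow(schedule))) {
    idx <- which(t >= seg_start[s] &
                 t < seg_start[s] + schedule$duration_s[s] + dt / 2)
    a_ss[idx] <- a_ss_fun(log(lum[s]))
  }
  decay <- exp(-dt / pm$tau_s)
  pupil <- numeric(n)
  pupil[1] <- a_ss[1]
  for (i in 2:n) pupil[i] <- a_ss[i] + (pupil[i - 1] - a_ss[i]) * decay

  events_df <- if (length(events)) {
    ed <- do.call(rbind, events)
    ed[order(ed$onset), , drop = FALSE]
  } else data.frame(type = character(0), onset = numeric(0),
                    offset = numeric(0), amplitude = numeric(0),
                    direction = numeric(0))
  rownames(events_df) <- NULL

  in_blink <- function(tt, pad = 0) .in_events(tt,
    if (nrow(blinks)) data.frame(onset = blinks$onset, offset = blinks$offset)
    else NULL, pad)

  ## --- tracker A: exact constant-rate monocular sampling
  t_a <- seq(0, duration, by = 1 / config$tracker_a_rate)
  ax <- stats::approx(t, x, t_a, rule = 2)$y
  ay <- stats::approx(t, y, t_a, rule = 2)$y
  if (config$measurement_noise_a > 0) {
    ax <- ax + stats::rnorm(length(t_a), 0, config$measurement_noise_a)
    ay <- ay + stats::rnorm(length(t_a), 0, config$measurement_noise_a)
  }
  ap <- stats::approx(t, pupil, t_a, rule = 2)$y
  bl_a <- in_blink(t_a)
  ap[bl_a] <- NA_real_
  ## position hold during pupil loss (device outputs last valid position)
  if (any(bl_a)) {
    hold <- cummax(ifelse(!bl_a, seq_along(t_a), 0L))
    hold[hold == 0L] <- which(!bl_a)[1]
    ax[bl_a] <- ax[hold[bl_a]]; ay[bl_a] <- ay[hold[bl_a]]
  }
  stream_a <- sample_stream(t_s = t_a, x_deg = ax, y_deg = ay,
                            pupil = ap, confidence = NA_real_, valid = TRUE)

  ## --- tracker B: dual-camera fusion
  phase <- if (identical(config$camera_phase, "random"))
    stats::runif(1) else config$camera_phase
  fused <- degrade_to_dual_camera(t, x, y, config$tracker_b_camera_rate,
                                  phase, mode = config$fusion)
  bx <- fused$x_deg; by <- fused$y_deg
  if (config$measurement_noise_b > 0) {
    bx <- bx + stats::rnorm(nrow(fused), 0, config$measurement_noise_b)
    by <- by + stats::rnorm(nrow(fused), 0, config$measurement_noise_b)
  }
  bp <- stats::approx(t, pupil, fused$t_s, rule = 2)$y
  conf <- stats::runif(nrow(fused), 0.92, 1.0)
  bl_b <- in_blink(fused$t_s)
  if (any(bl_b)) {
    conf[bl_b] <- stats::runif(sum(bl_b), 0.01, 0.08)
    ## lid-closure artifact: downward ramp in y
    for (i in seq_len(nrow(blinks))) {
      sel <- which(fused$t_s >= blinks$onset[i] & fused$t_s < blinks$offset[i])
      if (length(sel) == 0) next
      prog <- (fused$t_s[sel] - blinks$onset[i]) /
        (blinks$offset[i] - blinks$onset[i])
      by[sel] <- by[sel] - 3 * sin(pi * pmin(prog, 1))
    }
  }
  stream_b <- sample_stream(t_s = fused$t_s, x_deg = bx, y_deg = by,
                            pupil = bp, confidence = conf, valid = TRUE)

  ## --- trigger log: one message per segment boundary; tracker B runs on
  ## its own clock with a slope offset and a 10 ms acquisition delay
  slope_b <- 1 + 5e-5
  offset_b <- 3.0
  t_stim <- c(seg_start, duration)
  triggers <- data.frame(msg = c(paste0("SEG_", seq_len(nrow(schedule))),
                                 "END"),
                         t_stim = t_stim, t_a = t_stim,
                         t_b = slope_b * t_stim + offset_b)
  stream_b$t_s <- slope_b * (stream_b$t_s + 0.010) + offset_b

  ground_truth <- list(events = events_df,
                       latent_path = data.frame(t = t, x_deg = x, y_deg = y),
                       pursuit_params = if (length(pursuit_params))
                         do.call(rbind, pursuit_params)
                       else NULL,
                       pupil_trace = data.frame(t = t, area = pupil),
                       camera_phase = phase,
                       clock_b = c(slope = slope_b, offset = offset_b,
                                   delay = 0.010))
  list(stream_a = stream_a, stream_b = stream_b, triggers = triggers,
       ground_truth = ground_truth)
}

#' Write a simulated session to disk
#'
#' Streams as CSV in the sample-stream contract, trigger log as CSV, ground
#' truth as JSON.
#'
#' @param session result of \code{\link{simulate_session}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_samples(session$stream_a, file.path(dir, "stream_a.csv"))
  write_samples(session$stream_b, file.path(dir, "stream_b.csv"))
  utils::write.csv(session$triggers, file.path(dir, "triggers.csv"),
                   row.names = FALSE)
  gt <- session$ground_truth
  gt$latent_path <- NULL  # dense path kept in memory only
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a simulation configuration from YAML
#'
#' Reads a YAML mapping whose keys are arguments of
#' \code{\link{simulation_config}} and builds the configuration; unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return a \code{simulation_config}.
#' @export
read_simulation_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(simulation_config, vals)
}
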