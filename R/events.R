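#' Detector configuration
#'
#' Parameters of the velocity-threshold saccade classifier and the blink /
#' fixation labelling rules. The velocity threshold multiplier
#' \code{lambda = 5} is the battery's setting for general saccade
#' classification (the same classifier run on fixation-task segments alone
#' recovers microsaccades). Blink events are padded by +-100 ms before
#' fixation labelling; fixations shorter than 50 ms are removed.
#'
#' @param lambda velocity-threshold multiplier (> 0), default 5.
#' @param min_saccade_samples minimum run length of suprathreshold samples,
#'   default 3.
#' @param merge_gap_samples runs separated by at most this many samples are
#'   merged, default 1.
#' @param blink_pad seconds of padding applied around each blink, default
#'   0.100.
#' @param min_fixation minimum fixation duration in seconds, default 0.050.
#' @param sigma_floor lower bound on the per-axis noise estimate in deg/s,
#'   protects against a zero threshold on noiseless synthetic input.
#' @param confidence_smooth_window moving-average window (s) for the
#'   confidence-based blink detector, default 0.15.
#' @param confidence_filter_threshold fraction of the smoothed-confidence
#'   derivative range used as the blink on/offset threshold, default 0.5.
#' @param min_blink_samples minimum missing-pupil run length for the
#'   gap-based blink detector, default 2.
#' @param refine_boundaries logical; delimit each saccade with a second,
#'   lower threshold (default TRUE). The suprathreshold crossing at
#'   \code{lambda} necessarily lags the true movement onset, so after
#'   detection the onset is walked backward (and the offset forward) to the
#'   first sample whose criterion value falls below the \code{onset_lambda}
#'   level — the standard dual-threshold delimitation of the velocity pulse
#'   foot.
#' @param onset_lambda multiplier of the delimitation threshold (default 3;
#'   must not exceed \code{lambda}).
#' @return list of class \code{detector_config}.
#' @export
detector_config <- function(lambda = 5, min_saccade_samples = 3,
                            merge_gap_samples = 1, blink_pad = 0.100,
                            min_fixation = 0.050, sigma_floor = 1e-6,
                            confidence_smooth_window = 0.15,
                            confidence_filter_threshold = 0.5,
                            min_blink_samples = 2,
                            refine_boundaries = TRUE,
                            onset_lambda = 3) {
  stopifnot(lambda > 0, blink_pad >= 0, min_fixation >= 0,
            min_saccade_samples >= 1, merge_gap_samples >= 0)
  structure(list(lambda = lambda,
                 min_saccade_samples = min_saccade_samples,
                 merge_gap_samples = merge_gap_samples,
                 blink_pad = blink_pad, min_fixation = min_fixation,
                 sigma_floor = sigma_floor,
                 confidence_smooth_window = confidence_smooth_window,
                 confidence_filter_threshold = confidence_filter_threshold,
                 min_blink_samples = min_blink_samples,
                 refine_boundaries = refine_boundaries,
                 onset_lambda = onset_lambda),
            class = "detector_config")
}

.empty_events <- function() {
  data.frame(type = character(0), onset = numeric(0), offset = numeric(0),
             amplitude = numeric(0), peak_velocity = numeric(0),
             mean_x = numeric(0), mean_y = numeric(0),
             n_samples = integer(0), stringsAsFactors = FALSE)
}

.event_row <- function(type, onset, offset, amplitude = NA_real_,
                       peak_velocity = NA_real_, mean_x = NA_real_,
                       mean_y = NA_real_, n_samples = NA_integer_) {
  data.frame(type = type, onset = onset, offset = offset,
             amplitude = amplitude, peak_velocity = peak_velocity,
             mean_x = mean_x, mean_y = mean_y, n_samples = n_samples,
             stringsAsFactors = FALSE)
}

#' Per-sample gaze velocity by the 5-point difference kernel
#'
#' v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 * dt) per axis, the
#' moving-average difference kernel of the velocity-threshold classifier;
#' exact for linear signals and noise-suppressing. The first and last two
#' samples inherit the velocity of the nearest interior sample. Requires a
#' constant sampling rate.
#'
#' @param stream a \code{sample_stream} at constant rate (>= 5 samples).
#' @return data frame \code{vx, vy} in deg/s, one row per sample.
#' @export
compute_velocity <- function(stream) {
  n <- nrow(stream)
  if (n < 5) stop("need at least 5 samples")
  dt <- stats::median(diff(stream$t_s))
  kern <- function(x) {
    v <- rep(NA_real_, n)
    i <- 3:(n - 2)
    v[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
    v[1:2] <- v[3]
    v[(n - 1):n] <- v[n - 2]
    v
  }
  data.frame(vx = kern(stream$x_deg), vy = kern(stream$y_deg))
}

## median-based robust SD estimate: sqrt(median(v^2) - median(v)^2)
.sigma_median <- function(v) {
  sqrt(max(0, stats::median(v^2, na.rm = TRUE) -
             stats::median(v, na.rm = TRUE)^2))
}

## contiguous runs of TRUE; returns matrix with columns start, end
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Velocity-threshold (elliptic criterion) saccade detection
#'
#' Estimates a per-axis noise level with the median-based estimator
#' sigma = sqrt(median(v^2) - median(v)^2), sets thresholds
#' eta = lambda * max(sigma, sigma_floor) per axis, and flags samples with
#' (vx/eta_x)^2 + (vy/eta_y)^2 > 1. Runs of at least
#' \code{min_saccade_samples} flagged samples become saccade events; runs
#' separated by at most \code{merge_gap_samples} samples are merged.
#' Amplitude is the angular distance between the event's first and last
#' sample positions; peak velocity the maximum 2D speed inside the event.
#' Samples flagged in \code{exclude} (e.g. padded blink samples) are removed
#' from both the threshold estimate and the runs.
#'
#' Run on a sustained-fixation segment only, the same operation recovers
#' microsaccades.
#'
#' @param stream constant-rate \code{sample_stream}.
#' @param cfg a \code{\link{detector_config}}.
#' @param velocities optional precomputed output of
#'   \code{\link{compute_velocity}}.
#' @param exclude logical vector, samples to ignore (default none).
#' @return event table (saccades) with half-open [onset, offset) intervals.
#' @export
detect_saccades <- function(stream, cfg = detector_config(),
                            velocities = NULL, exclude = NULL) {
  if (is.null(velocities)) velocities <- compute_velocity(stream)
  n <- nrow(stream)
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  vx <- velocities$vx; vy <- velocities$vy
  ok <- !exclude & is.finite(vx) & is.finite(vy)
  eta_x <- cfg$lambda * max(.sigma_median(vx[ok]), cfg$sigma_floor)
  eta_y <- cfg$lambda * max(.sigma_median(vy[ok]), cfg$sigma_floor)
  crit <- (vx / eta_x)^2 + (vy / eta_y)^2 > 1
  crit[!ok] <- FALSE
  if (mean(crit, na.rm = TRUE) > 0.5)
    warning("more than 50% of samples above threshold: degenerate threshold")
  runs <- .runs(crit)
  if (nrow(runs) > 1 && cfg$merge_gap_samples > 0) {
    keep <- TRUE
    merged <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[i, "start"] - last["end"] - 1 <= cfg$merge_gap_samples)
        merged[[length(merged)]] <- c(start = unname(last["start"]),
                                      end = unname(runs[i, "end"]))
      else merged[[length(merged) + 1]] <- runs[i, ]
    }
    runs <- do.call(rbind, merged)
  }
  runs <- runs[runs[, "end"] - runs[, "start"] + 1 >= cfg$min_saccade_samples, ,
               drop = FALSE]
  if (nrow(runs) == 0) return(.empty_events())
  if (isTRUE(cfg$refine_boundaries)) {
    z <- (vx / eta_x)^2 + (vy / eta_y)^2
    z_on <- (min(cfg$onset_lambda, cfg$lambda) / cfg$lambda)^2
    prev_end <- 0L
    for (i in seq_len(nrow(runs))) {
      a <- runs[i, "start"]; b <- runs[i, "end"]
      while (a - 1 > prev_end && ok[a - 1] && !is.na(z[a - 1]) &&
             z[a - 1] > z_on) a <- a - 1
      nxt <- if (i < nrow(runs)) runs[i + 1, "start"] else n + 1L
      while (b + 1 < nxt && ok[b + 1] && !is.na(z[b + 1]) &&
             z[b + 1] > z_on) b <- b + 1
      runs[i, "start"] <- a; runs[i, "end"] <- b
      prev_end <- b
    }
  }
  dt <- stats::median(diff(stream$t_s))
  ev <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs[i, "start"]; b <- runs[i, "end"]
    .event_row("saccade",
               onset = stream$t_s[a],
               offset = stream$t_s[b] + dt,
               amplitude = angular_distance(stream$x_deg[a], stream$y_deg[a],
                                            stream$x_deg[b], stream$y_deg[b]),
               peak_velocity = max(sqrt(vx[a:b]^2 + vy[a:b]^2)),
               mean_x = mean(stream$x_deg[a:b]),
               mean_y = mean(stream$y_deg[a:b]),
               n_samples = b - a + 1L)
  })
  out <- do.call(rbind, ev)
  attr(out, "thresholds") <- c(eta_x = eta_x, eta_y = eta_y)
  out
}

#' Confidence-based blink detection
#'
#' For trackers that signal blinks by a drop in per-sample confidence: the
#' confidence trace is smoothed with a moving average over
#' \code{confidence_smooth_window} seconds, differentiated, and thresholded
#' at \code{confidence_filter_threshold} times the derivative's absolute
#' range. A strong negative excursion is a blink-onset candidate, a strong
#' positive one an offset candidate. Among consecutive onset candidates only
#' the last is kept, and an onset without a following offset is discarded —
#' so a blink can only start if it also ends.
#'
#' @param stream \code{sample_stream} with a confidence channel.
#' @param cfg a \code{\link{detector_config}}.
#' @return event table (blinks).
#' @export
detect_blinks_confidence <- function(stream, cfg = detector_config()) {
  conf <- stream$confidence
  if (all(is.na(conf)))
    stop("no confidence channel; use detect_blinks_gap() instead")
  t <- stream$t_s
  dt <- stats::median(diff(t))
  w <- max(1L, round(cfg$confidence_smooth_window / dt))
  ## moving average with edge padding (replicate end values)
  padded <- c(rep(conf[1], w), conf, rep(conf[length(conf)], w))
  sm <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))
  sm <- sm[(w + 1):(w + length(conf))]
  d <- c(0, diff(sm)) / dt
  thr <- cfg$confidence_filter_threshold * max(abs(d), na.rm = TRUE)
  if (!is.finite(thr) || thr <= 0) return(.empty_events())
  onset_cand <- .runs(d < -thr)
  offset_cand <- .runs(d > thr)
  if (nrow(onset_cand) == 0 || nrow(offset_cand) == 0) return(.empty_events())
  events <- list()
  i <- 1
  while (i <= nrow(onset_cand)) {
    ## consume consecutive onsets with no offset in between: keep the last
    j <- i
    while (j < nrow(onset_cand) &&
           !any(offset_cand[, "start"] > onset_cand[j, "end"] &
                offset_cand[, "start"] < onset_cand[j + 1, "start"]))
      j <- j + 1
    on_idx <- onset_cand[j, "start"]
    off_rows <- which(offset_cand[, "start"] > onset_cand[j, "end"])
    if (length(off_rows) == 0) break  # onset without offset: discard
    off_idx <- offset_cand[off_rows[1], "end"]
    events[[length(events) + 1]] <-
      .event_row("blink", onset = t[on_idx], offset = t[off_idx] + dt,
                 n_samples = off_idx - on_idx + 1L)
    i <- j + 1
    while (i <= nrow(onset_cand) && onset_cand[i, "start"] <= off_idx)
      i <- i + 1
  }
  if (length(events) == 0) return(.empty_events())
  do.call(rbind, events)
}

#' Gap-based blink detection
#'
#' For trackers that report blinks as missing pupil: maximal runs of samples
#' with no detected pupil (NA or zero area) of at least
#' \code{min_blink_samples} become blink events. Runs are not merged.
#'
#' @param stream \code{sample_stream} with a pupil channel.
#' @param cfg a \code{\link{detector_config}}.
#' @return event table (blinks).
#' @export
detect_blinks_gap <- function(stream, cfg = detector_config()) {
  missing <- is.na(stream$pupil) | stream$pupil <= 0
  runs <- .runs(missing)
  runs <- runs[runs[, "end"] - runs[, "start"] + 1 >= cfg$min_blink_samples, ,
               drop = FALSE]
  if (nrow(runs) == 0) return(.empty_events())
  dt <- stats::median(diff(stream$t_s))
  do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    .event_row("blink", onset = stream$t_s[runs[i, "start"]],
               offset = stream$t_s[runs[i, "end"]] + dt,
               n_samples = runs[i, "end"] - runs[i, "start"] + 1L)
  }))
}

## logical membership of sample times in half-open [onset, offset) intervals
.in_events <- function(t, events, pad = 0) {
  flag <- rep(FALSE, length(t))
  if (is.null(events) || nrow(events) == 0) return(flag)
  for (i in seq_len(nrow(events)))
    flag <- flag | (t >= events$onset[i] - pad & t < events$offset[i] + pad)
  flag
}

#' Label every sample and assemble the full event table
#'
#' Blink events are padded by +-\code{blink_pad} seconds; padded blink
#' samples win over saccade claims (no pupil means position is
#' untrustworthy). All samples that are neither blink nor saccade are
#' fixation samples; maximal fixation runs shorter than \code{min_fixation}
#' are removed and their samples labelled \code{none}. Mean fixation
#' position is the mean of member samples in degrees.
#'
#' @param stream \code{sample_stream}.
#' @param saccades,blinks event tables from the detectors (either may be
#'   empty).
#' @param cfg a \code{\link{detector_config}}.
#' @return list with \code{stream} (labels filled) and \code{events}
#'   (fixation, saccade and padded blink events, ordered by onset).
#' @export
label_fixations <- function(stream, saccades, blinks, cfg = detector_config()) {
  t <- stream$t_s
  dt <- stats::median(diff(t))
  in_blink <- .in_events(t, blinks, pad = cfg$blink_pad)
  in_sacc <- .in_events(t, saccades) & !in_blink
  label <- rep("fixation", length(t))
  label[in_sacc] <- "saccade"
  label[in_blink] <- "blink"
  fix_runs <- .runs(label == "fixation")
  events <- list()
  if (nrow(fix_runs) > 0) {
    for (i in seq_len(nrow(fix_runs))) {
      a <- fix_runs[i, "start"]; b <- fix_runs[i, "end"]
      dur <- t[b] + dt - t[a]
      if (dur < cfg$min_fixation) {
        label[a:b] <- "none"
      } else {
        events[[length(events) + 1]] <-
          .event_row("fixation", onset = t[a], offset = t[b] + dt,
                     amplitude = 0,
                     mean_x = mean(stream$x_deg[a:b], na.rm = TRUE),
                     mean_y = mean(stream$y_deg[a:b], na.rm = TRUE),
                     n_samples = b - a + 1L)
      }
    }
  }
  fix_events <- if (length(events)) do.call(rbind, events) else .empty_events()
  ## padded blink intervals as events
  blink_events <- .empty_events()
  if (!is.null(blinks) && nrow(blinks) > 0) {
    blink_events <- blinks
    blink_events$onset <- blinks$onset - cfg$blink_pad
    blink_events$offset <- blinks$offset + cfg$blink_pad
  }
  sacc_events <- if (!is.null(saccades) && nrow(saccades) > 0) {
    keep <- !vapply(seq_len(nrow(saccades)), function(i) {
      any(saccades$onset[i] < blink_events$offset &
          saccades$offset[i] > blink_events$onset)
    }, logical(1))
    saccades[keep, , drop = FALSE]
  } else .empty_events()
  all_events <- rbind(fix_events, sacc_events, blink_events)
  all_events <- all_events[order(all_events$onset), , drop = FALSE]
  rownames(all_events) <- NULL
  stream$label <- label
  list(stream = .as_stream(stream), events = all_events)
}

#' Match events across two trackers
#'
#' Events match when their [onset, offset) intervals overlap or one contains
#' the other. Pairing is greedy one-to-one by largest temporal overlap.
#'
#' @param events_a,events_b event tables on a common clock (typically one
#'   event type each).
#' @return list with \code{pairs} (data frame of indices \code{a}, \code{b}
#'   and \code{overlap} seconds), \code{unmatched_a}, \code{unmatched_b},
#'   and counts \code{n_hit}, \code{n_miss_a}, \code{n_miss_b}.
#' @export
match_events <- function(events_a, events_b) {
  na <- nrow(events_a); nb <- nrow(events_b)
  if (na == 0 || nb == 0) {
    return(list(pairs = data.frame(a = integer(0), b = integer(0),
                                   overlap = numeric(0)),
                unmatched_a = seq_len(na), unmatched_b = seq_len(nb),
                n_hit = 0L, n_miss_a = na, n_miss_b = nb))
  }
  ov <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    ov[i, ] <- pmax(0, pmin(events_a$offset[i], events_b$offset) -
                       pmax(events_a$onset[i], events_b$onset))
  }
  pairs <- list()
  repeat {
    m <- which.max(ov)
    if (ov[m] <= 0) break
    i <- (m - 1) %% na + 1
    j <- (m - 1) %/% na + 1
    pairs[[length(pairs) + 1]] <- data.frame(a = i, b = j, overlap = ov[m])
    ov[i, ] <- 0; ov[, j] <- 0
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
  else data.frame(a = integer(0), b = integer(0), overlap = numeric(0))
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(na), pairs$a),
       unmatched_b = setdiff(seq_len(nb), pairs$b),
       n_hit = nrow(pairs),
       n_miss_a = na - nrow(pairs),
       n_miss_b = nb - nrow(pairs))
}
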