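#' RMS precision: inter-sample angular distance
#'
#' theta_RMS = sqrt( (1/n) * sum_i d(s_i, s_{i-1})^2 ) over the consecutive
#' sample pairs of one fixation, with d the great-circle angular distance.
#' Measures sample-to-sample noise.
#'
#' @param x_deg,y_deg gaze coordinates of one fixation's samples, degrees.
#' @return degrees (>= 0).
#' @export
precision_rms <- function(x_deg, y_deg) {
  n <- length(x_deg)
  if (n < 2) stop("need at least 2 samples")
  d <- angular_distance(x_deg[-1], y_deg[-1], x_deg[-n], y_deg[-n])
  sqrt(mean(d^2))
}

#' SD precision: angular spread around the mean position
#'
#' theta_sd = sqrt( (1/n) * sum_i d(s_i, s_bar)^2 ), the RMS angular distance
#' of samples to the mean sample position. Measures fixation spread.
#'
#' @inheritParams precision_rms
#' @return degrees (>= 0).
#' @export
precision_sd <- function(x_deg, y_deg) {
  if (length(x_deg) < 2) stop("need at least 2 samples")
  d <- angular_distance(x_deg, y_deg, mean(x_deg), mean(y_deg))
  sqrt(mean(d^2))
}

#' Per-target spatial accuracy from confirmed fixations
#'
#' For each instructed target, selects the fixation the participant was in
#' when confirming by key press — the last fixation overlapping the press or
#' ending at most \code{press_slack} seconds before it — and returns the
#' angular offset between the fixation's mean position and the target. The
#' alternative \code{method = "window_mean"} (head-roll rule) instead uses
#' the winsorized mean sample position over the \code{window} seconds before
#' the press.
#'
#' @param fixations fixation event table (from \code{\link{label_fixations}}).
#' @param targets data frame with columns \code{x_deg}, \code{y_deg} and
#'   \code{t_press} (confirmation time, seconds).
#' @param method "last_fixation" (default) or "window_mean".
#' @param stream required for \code{window_mean}: the labelled sample stream.
#' @param window seconds before the press used by \code{window_mean},
#'   default 0.5.
#' @param press_slack tolerance for fixations ending just before the press,
#'   default 0.05 s.
#' @param gamma winsorization fraction for \code{window_mean}.
#' @return data frame \code{targets} with added columns \code{offset_deg},
#'   \code{fix_x}, \code{fix_y}; targets with no usable fixation get NA and
#'   are counted in attribute \code{"n_skipped"}.
#' @export
target_accuracy <- function(fixations, targets,
                            method = c("last_fixation", "window_mean"),
                            stream = NULL, window = 0.5, press_slack = 0.05,
                            gamma = 0.20) {
  method <- match.arg(method)
  out <- targets
  out$offset_deg <- NA_real_
  out$fix_x <- NA_real_
  out$fix_y <- NA_real_
  for (i in seq_len(nrow(targets))) {
    tp <- targets$t_press[i]
    if (method == "last_fixation") {
      cand <- which(fixations$onset <= tp &
                    fixations$offset + press_slack > tp)
      if (length(cand) == 0)
        cand <- which(fixations$offset <= tp + press_slack)
      if (length(cand) == 0) next
      j <- cand[which.max(fixations$onset[cand])]
      fx <- fixations$mean_x[j]; fy <- fixations$mean_y[j]
    } else {
      stopifnot(!is.null(stream))
      sel <- stream$t_s >= tp - window & stream$t_s < tp &
        stream$label == "fixation"
      if (sum(sel) < 2) next
      fx <- winsorized_mean(stream$x_deg[sel], gamma, ci = "none")$mean
      fy <- winsorized_mean(stream$y_deg[sel], gamma, ci = "none")$mean
    }
    out$fix_x[i] <- fx
    out$fix_y[i] <- fy
    out$offset_deg[i] <- angular_distance(fx, fy,
                                          targets$x_deg[i], targets$y_deg[i])
  }
  attr(out, "n_skipped") <- sum(is.na(out$offset_deg))
  out
}

#' Winsorized group accuracy over the targets-blocks-subjects hierarchy
#'
#' Aggregation order is fixed: winsorized mean over targets within each
#' block, then over blocks within each subject, then over subjects for the
#' group value with its confidence interval (the IQR of subject means, not
#' the mean IQR).
#'
#' @param df data frame with columns \code{offset_deg}, \code{block},
#'   \code{subject} (one row per target).
#' @param gamma winsorization fraction per tail.
#' @param ... passed to \code{\link{winsorized_hierarchy}}.
#' @return list as from \code{\link{winsorized_hierarchy}}; \code{per_unit}
#'   holds the per-subject means.
#' @export
accuracy_summary <- function(df, gamma = 0.20, ...) {
  df <- df[!is.na(df$offset_deg), , drop = FALSE]
  winsorized_hierarchy(df, "offset_deg", c("block", "subject"), gamma, ...)
}

#' Calibration-decay summary by paired winsorized differences
#'
#' For each subject, the difference of accuracy at each later timepoint
#' minus the baseline timepoint is formed (subjects missing a timepoint are
#' dropped from that contrast); the group winsorized mean and confidence
#' interval of those paired differences is reported per timepoint.
#'
#' @param df data frame with columns \code{subject}, \code{timepoint},
#'   \code{accuracy} (one row per subject x timepoint, already aggregated
#'   within subject).
#' @param baseline the timepoint label serving as baseline.
#' @param gamma winsorization fraction.
#' @param ci_level confidence level.
#' @return data frame, one row per non-baseline timepoint: \code{timepoint},
#'   \code{diff} (winsorized mean of paired differences), \code{ci_lo},
#'   \code{ci_hi}, \code{n}.
#' @export
decay_summary <- function(df, baseline, gamma = 0.20, ci_level = 0.95) {
  tps <- setdiff(unique(df$timepoint), baseline)
  base <- df[df$timepoint == baseline, c("subject", "accuracy")]
  names(base)[2] <- "base"
  rows <- lapply(tps, function(tp) {
    cur <- df[df$timepoint == tp, c("subject", "accuracy")]
    m <- merge(cur, base, by = "subject")
    if (nrow(m) == 0)
      return(data.frame(timepoint = tp, diff = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n = 0L))
    d <- m$accuracy - m$base
    w <- winsorized_mean(d, gamma, ci_level = ci_level)
    data.frame(timepoint = tp, diff = w$mean, ci_lo = w$ci[1],
               ci_hi = w$ci[2], n = w$n)
  })
  do.call(rbind, rows)
}

#' Free-viewing fixation statistics
#'
#' Per image: number of fixations (excluding the first, which sits on the
#' pre-image fixation cross), fixation durations, and the amplitudes of the
#' saccades between retained fixations.
#'
#' @param events event table for one image presentation, ordered by onset.
#' @return list with \code{n_fixations}, \code{durations} (s),
#'   \code{amplitudes} (deg, from the saccade events).
#' @export
freeview_stats <- function(events) {
  fix <- events[events$type == "fixation", , drop = FALSE]
  if (nrow(fix) > 0) fix <- fix[-1, , drop = FALSE]  # drop cross fixation
  sac <- events[events$type == "saccade", , drop = FALSE]
  list(n_fixations = nrow(fix),
       durations = fix$offset - fix$onset,
       amplitudes = sac$amplitude)
}

#' Gaussian-smoothed fixation density map
#'
#' Bins fixation positions into a 2D histogram over the effective screen
#' area and convolves it with an isotropic Gaussian kernel of the given SD
#' in degrees (converted to pixels through the geometry). Mass is conserved
#' up to truncation at the map boundary.
#'
#' @param fix_x,fix_y fixation positions, degrees.
#' @param geom a \code{\link{screen_geometry}}.
#' @param kernel_sd Gaussian SD in degrees, default 3.
#' @param bin_px histogram bin size in pixels, default 10.
#' @return list with \code{density} (matrix, columns = x), \code{x_px},
#'   \code{y_px} bin centers.
#' @export
fixation_density <- function(fix_x, fix_y, geom, kernel_sd = 3, bin_px = 10) {
  px <- deg_to_px(fix_x, geom)
  py <- deg_to_px(fix_y, geom)
  half_w <- geom$effective_width_px / 2
  half_h <- geom$effective_height_px / 2
  xb <- seq(-half_w, half_w + bin_px, by = bin_px)
  yb <- seq(-half_h, half_h + bin_px, by = bin_px)
  ix <- findInterval(px, xb, rightmost.closed = TRUE)
  iy <- findInterval(py, yb, rightmost.closed = TRUE)
  keep <- ix >= 1 & ix < length(xb) & iy >= 1 & iy < length(yb)
  h <- matrix(0, nrow = length(yb) - 1, ncol = length(xb) - 1)
  for (k in which(keep)) h[iy[k], ix[k]] <- h[iy[k], ix[k]] + 1
  ## separable Gaussian convolution; kernel SD in bins
  sd_px <- deg_to_px(kernel_sd, geom)   # small-angle: SD near center
  sd_bins <- sd_px / bin_px
  half <- max(1L, ceiling(3 * sd_bins))
  kern <- stats::dnorm(-half:half, sd = sd_bins)
  kern <- kern / sum(kern)
  conv1 <- function(v) {
    out <- stats::filter(c(rep(0, half), v, rep(0, half)), kern, sides = 2)
    as.numeric(out)[(half + 1):(half + length(v))]
  }
  sm <- apply(h, 2, conv1)               # smooth columns (y)
  sm <- t(apply(sm, 1, conv1))           # smooth rows (x)
  list(density = sm,
       x_px = xb[-length(xb)] + bin_px / 2,
       y_px = yb[-length(yb)] + bin_px / 2)
}
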