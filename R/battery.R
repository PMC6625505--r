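#' Fixation grid targets
#'
#' Equally spaced crossing points of an n_x x n_y grid spanning the stated
#' degree ranges (defaults: 7 x 7 over -18.2..18.2 deg horizontally and
#' -7.7..7.7 deg vertically, 49 points).
#'
#' @param n_x,n_y grid dimensions.
#' @param x_range,y_range two-element degree ranges.
#' @return data frame \code{x_deg}, \code{y_deg}, one row per crossing.
#' @export
make_grid <- function(n_x = 7, n_y = 7,
                      x_range = c(-18.2, 18.2), y_range = c(-7.7, 7.7)) {
  xs <- seq(x_range[1], x_range[2], length.out = n_x)
  ys <- seq(y_range[1], y_range[2], length.out = n_y)
  expand.grid(x_deg = xs, y_deg = ys, KEEP.OUT.ATTRS = FALSE)
}

#' 13-point calibration subset of the large grid
#'
#' Standard calibration layout spanning the whole screen: the center, the
#' four corners, the four edge midpoints, and the four mid-diagonal points
#' halfway between center and corners (snapped to grid crossings).
#'
#' @param grid output of \code{\link{make_grid}} (7 x 7 assumed).
#' @return data frame of 13 rows, subset of \code{grid}.
#' @export
subset_13 <- function(grid = make_grid()) {
  xs <- sort(unique(grid$x_deg)); ys <- sort(unique(grid$y_deg))
  n_x <- length(xs); n_y <- length(ys)
  mid_x <- xs[(n_x + 1) / 2]; mid_y <- ys[(n_y + 1) / 2]
  qx <- xs[c((n_x + 3) / 4, (3 * n_x + 1) / 4)]   # quarter columns (2, 6)
  qy <- ys[c((n_y + 3) / 4, (3 * n_y + 1) / 4)]
  pts <- rbind(
    c(mid_x, mid_y),
    expand.grid(x_deg = range(xs), y_deg = range(ys)),       # corners
    data.frame(x_deg = c(mid_x, mid_x, min(xs), max(xs)),    # edge midpoints
               y_deg = c(min(ys), max(ys), mid_y, mid_y)),
    expand.grid(x_deg = qx, y_deg = qy))                     # mid-diagonals
  out <- as.data.frame(pts)
  names(out) <- c("x_deg", "y_deg")
  rownames(out) <- NULL
  out
}

.norm_entropy <- function(values, breaks) {
  h <- tabulate(cut(values, breaks, include.lowest = TRUE, labels = FALSE),
                nbins = length(breaks) - 1)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(breaks) - 1)
}

#' Entropy-maximizing constrained randomization of grid targets
#'
#' Orders the grid targets so the implied saccade sequence has amplitude and
#' angle distributions as uniform as possible: among \code{n_iter} random
#' permutations (anchored to start and end at the center target), the one
#' maximizing 0.55 * H_norm(amplitude histogram, 17 x 1-degree bins) +
#' 0.45 * H_norm(angle histogram, 10 x 36-degree bins) is returned, where
#' H_norm is Shannon entropy normalized by log(number of bins). Seeded and
#' deterministic; the best objective is non-decreasing in \code{n_iter}.
#'
#' @param points data frame \code{x_deg}, \code{y_deg}.
#' @param n_iter number of candidate permutations, default 10000.
#' @param amp_breaks amplitude histogram breaks, degrees (17 1-degree bins).
#' @param angle_breaks angle histogram breaks, degrees (10 36-degree bins).
#' @param weights c(amplitude, angle) entropy weights, default c(0.55, 0.45).
#' @param seed integer seed.
#' @param center_index row of \code{points} anchored at both sequence ends;
#'   default the point nearest (0, 0).
#' @return list: \code{order} (row indices into \code{points}, center first
#'   and last), \code{objective}, \code{n_iter}.
#' @export
constrained_randomization <- function(points, n_iter = 10000,
                                      amp_breaks = 0:17,
                                      angle_breaks = seq(-180, 180, by = 36),
                                      weights = c(0.55, 0.45), seed = 1L,
                                      center_index = NULL) {
  stopifnot(nrow(points) >= 3, n_iter >= 1)
  if (is.null(center_index))
    center_index <- which.min(points$x_deg^2 + points$y_deg^2)
  others <- setdiff(seq_len(nrow(points)), center_index)
  objective <- function(ord) {
    dx <- diff(points$x_deg[ord]); dy <- diff(points$y_deg[ord])
    amp <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx) * 180 / pi
    weights[1] * .norm_entropy(amp, amp_breaks) +
      weights[2] * .norm_entropy(ang, angle_breaks)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  best <- NULL; best_obj <- -Inf
  for (i in seq_len(n_iter)) {
    ord <- c(center_index, sample(others), center_index)
    obj <- objective(ord)
    if (obj > best_obj) { best_obj <- obj; best <- ord }
  }
  list(order = best, objective = best_obj, n_iter = n_iter)
}

#' Luminance sequence for the pupil task
#'
#' Per block: the four target luminances (12.6, 47.8, 113.7, 226.0 cd/m2) in
#' seeded random order, each preceded by a black (0.5 cd/m2) baseline of 7 s
#' jittered +-0.25 s; targets shown 3 s jittered +-0.25 s.
#'
#' @param n_blocks number of blocks, default 6.
#' @param seed integer seed.
#' @param luminances target luminance levels, cd/m2.
#' @return data frame: \code{block}, \code{luminance}, \code{baseline_s},
#'   \code{stimulus_s}, in presentation order.
#' @export
pupil_schedule <- function(n_blocks = 6, seed = 1L,
                           luminances = c(12.6, 47.8, 113.7, 226.0)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(n_blocks), function(b) {
    lums <- sample(luminances)
    data.frame(block = b, luminance = lums,
               baseline_s = 7 + stats::runif(length(lums), -0.25, 0.25),
               stimulus_s = 3 + stats::runif(length(lums), -0.25, 0.25))
  })
  do.call(rbind, rows)
}

#' Step-ramp pursuit trial schedule
#'
#' Crossing of five target speeds (16, 18, 20, 22, 24 deg/s) and 24
#' equally spaced directions, each combination once, in seeded random order.
#' The target starts offset from the center by 0.2 s x speed against the
#' motion direction (so it crosses the center 0.2 s after motion onset) and
#' stops at 10 degrees eccentricity. Motion onset follows fixation
#' confirmation after a delay of 0.2 s plus an Exponential(mean 0.5 s)
#' draw truncated at 5 s (constant hazard).
#'
#' @param seed integer seed.
#' @param speeds target speeds, deg/s.
#' @param n_directions number of equally spaced directions.
#' @param stop_ecc trajectory end eccentricity, degrees.
#' @return data frame: \code{trial}, \code{speed}, \code{direction},
#'   \code{start_offset_deg}, \code{onset_delay_s}, \code{duration_s}.
#' @export
pursuit_schedule <- function(seed = 1L, speeds = c(16, 18, 20, 22, 24),
                             n_directions = 24, stop_ecc = 10) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  combos <- expand.grid(speed = speeds,
                        direction = seq(0, 360, length.out = n_directions + 1)[1:n_directions])
  combos <- combos[sample(nrow(combos)), , drop = FALSE]
  delay <- 0.2 + pmin(stats::rexp(nrow(combos), rate = 1 / 0.5), 5)
  data.frame(trial = seq_len(nrow(combos)),
             speed = combos$speed, direction = combos$direction,
             start_offset_deg = 0.2 * combos$speed,
             onset_delay_s = delay,
             duration_s = (stop_ecc + 0.2 * combos$speed) / combos$speed,
             row.names = NULL)
}

#' Head-movement task targets
#'
#' Roll: line orientations (-15, -10, -5, 0, 5, 10, 15) degrees. Yaw:
#' horizontal positions (-32.8, -16.7, 0, 16.7, 32.8) degrees. Each set is
#' emitted in seeded per-block random order.
#'
#' @param task "roll" or "yaw".
#' @param n_blocks number of blocks, default 6.
#' @param seed integer seed.
#' @return data frame \code{block}, \code{target} in presentation order.
#' @export
head_task_targets <- function(task = c("roll", "yaw"), n_blocks = 6,
                              seed = 1L) {
  task <- match.arg(task)
  set_ <- if (task == "roll") c(-15, -10, -5, 0, 5, 10, 15)
  else c(-32.8, -16.7, 0, 16.7, 32.8)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_blocks), function(b)
    data.frame(block = b, target = sample(set_))))
}
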