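#' Construct a gaze sample stream
#'
#' A sample stream is a data frame of time-ordered gaze samples on one
#' tracker's clock with the fixed column contract
#' \code{t_s, x_px, y_px, x_deg, y_deg, pupil, confidence, valid, label}.
#' Pixel coordinates are relative to the screen center (+x right, +y up);
#' degree coordinates are spherical visual degrees filled via
#' \code{\link{px_to_deg}}. \code{pupil} is an area or diameter in device
#' units; \code{confidence} in [0, 1] or NA where the tracker reports none;
#' \code{valid} flags samples the tracker did not mark corrupt. \code{label}
#' is one of \code{fixation, saccade, blink, none} once classified.
#'
#' @param t_s numeric, seconds, strictly increasing (after synchronization).
#' @param x_deg,y_deg gaze in degrees.
#' @param x_px,y_px gaze in pixels (optional; derived from degrees when a
#'   geometry is given).
#' @param pupil pupil size in device units (NA = no pupil detected).
#' @param confidence per-sample confidence, or NA.
#' @param valid logical validity flag.
#' @param label per-sample event label.
#' @param geom optional \code{\link{screen_geometry}} used to fill whichever
#'   of px/deg is missing.
#' @return data frame of class \code{sample_stream}.
#' @export
sample_stream <- function(t_s, x_deg = NULL, y_deg = NULL,
                          x_px = NULL, y_px = NULL,
                          pupil = NA_real_, confidence = NA_real_,
                          valid = TRUE, label = "none", geom = NULL) {
  n <- length(t_s)
  if (is.null(x_deg) && !is.null(x_px) && !is.null(geom)) {
    x_deg <- px_to_deg(x_px, geom); y_deg <- px_to_deg(y_px, geom)
  }
  if (is.null(x_px) && !is.null(x_deg) && !is.null(geom)) {
    x_px <- deg_to_px(x_deg, geom); y_px <- deg_to_px(y_deg, geom)
  }
  if (is.null(x_px)) { x_px <- rep(NA_real_, n); y_px <- rep(NA_real_, n) }
  if (is.null(x_deg)) { x_deg <- rep(NA_real_, n); y_deg <- rep(NA_real_, n) }
  df <- data.frame(t_s = t_s, x_px = x_px, y_px = y_px,
                   x_deg = x_deg, y_deg = y_deg,
                   pupil = rep_len(pupil, n),
                   confidence = rep_len(confidence, n),
                   valid = rep_len(valid, n),
                   label = rep_len(label, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("sample_stream", "data.frame")
  df
}

.as_stream <- function(df) {
  class(df) <- c("sample_stream", "data.frame")
  rownames(df) <- NULL
  df
}

#' Read / write sample streams in the CSV column contract
#'
#' @param path file path.
#' @return \code{read_samples}: a \code{sample_stream}.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "x_px", "y_px", "x_deg", "y_deg", "pupil", "confidence", "valid")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  if (is.null(df$label)) df$label <- "none"
  .as_stream(df)
}

#' @rdname read_samples
#' @param stream a \code{sample_stream}.
#' @export
write_samples <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE)
  invisible(path)
}

#' Read a trigger log (message id plus per-clock timestamps)
#'
#' Expected columns: \code{msg}, \code{t_stim}, and one timestamp column per
#' tracker clock (e.g. \code{t_a}, \code{t_b}).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_triggers <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Synchronize two recording clocks from shared trigger messages
#'
#' Fits to-clock times on from-clock times by ordinary least squares (or
#' Theil-Sen for glitch-prone logs) over the shared trigger messages, giving
#' the mapping t' = slope * t + offset - constant_delay. The constant delay
#' absorbs a fixed acquisition latency of the source device (10 ms for a
#' fused-camera tracker whose frames arrive one frame late).
#'
#' @param triggers data frame containing the two timestamp columns.
#' @param from,to names of the from-clock and to-clock timestamp columns.
#' @param constant_delay seconds subtracted from every mapped time
#'   (default 0).
#' @param method "ols" (default) or "theil_sen".
#' @return object of class \code{clock_map} with \code{slope}, \code{offset},
#'   \code{constant_delay}, \code{residual_sd}.
#' @export
synchronize_clocks <- function(triggers, from, to, constant_delay = 0,
                               method = c("ols", "theil_sen")) {
  method <- match.arg(method)
  x <- triggers[[from]]; y <- triggers[[to]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 shared trigger messages")
  if (method == "ols") {
    fit <- stats::lm.fit(cbind(1, x), y)
    offset <- fit$coefficients[1]; slope <- fit$coefficients[2]
    resid <- fit$residuals
  } else {
    ij <- utils::combn(length(x), 2)
    sl <- (y[ij[2, ]] - y[ij[1, ]]) / (x[ij[2, ]] - x[ij[1, ]])
    slope <- stats::median(sl, na.rm = TRUE)
    offset <- stats::median(y - slope * x)
    resid <- y - (slope * x + offset)
  }
  if (slope <= 0) stop("non-positive clock slope; check trigger pairing")
  residual_sd <- if (length(x) > 2) stats::sd(resid) else 0
  if (is.finite(residual_sd) && residual_sd > 0.005)
    warning(sprintf("sync residual SD %.1f ms > 5 ms: possible clock glitch",
                    residual_sd * 1000))
  structure(list(slope = unname(slope), offset = unname(offset),
                 constant_delay = constant_delay,
                 residual_sd = unname(residual_sd),
                 from = from, to = to, method = method),
            class = "clock_map")
}

#' @export
print.clock_map <- function(x, ...) {
  cat(sprintf("Clock map %s -> %s (%s): t' = %.9f * t + %.6f s - %.3f s delay; residual SD %.3g ms\n",
              x$from, x$to, x$method, x$slope, x$offset,
              x$constant_delay, x$residual_sd * 1000))
  invisible(x)
}

#' Apply or invert a clock map
#'
#' @param map a \code{clock_map}.
#' @param t times on the from-clock (or on the to-clock for the inverse).
#' @return mapped times.
#' @export
apply_clock_map <- function(map, t) map$slope * t + map$offset - map$constant_delay

#' @rdname apply_clock_map
#' @export
invert_clock_map <- function(map, t) (t + map$constant_delay - map$offset) / map$slope

#' Exclude invalid gaze samples
#'
#' Drops samples failing any of: pupil detected (pupil > 0 and not NA), gaze
#' point inside the effective monitor area, not marked corrupt
#' (\code{valid}). Removal counts per reason are attached as attribute
#' \code{"removals"}. Idempotent.
#'
#' @param stream a \code{sample_stream}.
#' @param geom a \code{\link{screen_geometry}} giving the effective extent.
#' @return cleaned \code{sample_stream}.
#' @export
exclude_bad_samples <- function(stream, geom) {
  no_pupil <- is.na(stream$pupil) | stream$pupil <= 0
  half_w <- geom$effective_width_px / 2
  half_h <- geom$effective_height_px / 2
  off <- is.na(stream$x_px) | is.na(stream$y_px) |
    abs(stream$x_px) > half_w | abs(stream$y_px) > half_h
  corrupt <- !stream$valid
  bad <- no_pupil | off | corrupt
  removals <- c(no_pupil = sum(no_pupil), offscreen = sum(off),
                corrupt = sum(corrupt), total = sum(bad))
  if (sum(bad) > 0.5 * nrow(stream))
    warning(sprintf("%.0f%% of samples removed", 100 * mean(bad)))
  out <- .as_stream(stream[!bad, , drop = FALSE])
  attr(out, "removals") <- removals
  out
}

#' Resample a stream to a constant rate with shape-preserving interpolation
#'
#' Piecewise cubic Hermite interpolation (PCHIP) of gaze position onto a
#' uniform time grid, the standard preparation for velocity-threshold event
#' classification of irregularly fused streams (default target 240 Hz
#' downstream). Gaps longer than \code{max_gap_s} (e.g. closed eyes) are not
#' interpolated across: the stream is split at such gaps and each segment is
#' resampled separately, so no samples are fabricated inside blinks. PCHIP
#' is monotone between knots, hence never overshoots the input extrema.
#'
#' @param stream a \code{sample_stream} (>= 4 samples per segment used).
#' @param rate target sampling rate, Hz.
#' @param max_gap_s gaps longer than this split interpolation segments
#'   (default 0.05 s).
#' @return resampled \code{sample_stream}; columns other than time/position
#'   are interpolated nearest-neighbour. Attribute \code{"segments"} gives
#'   the number of segments resampled.
#' @export
resample_constant_rate <- function(stream, rate, max_gap_s = 0.05) {
  if (rate <= 0) stop("rate must be positive")
  t <- stream$t_s
  if (length(t) < 4) stop("need at least 4 samples")
  gaps <- which(diff(t) > max_gap_s)
  starts <- c(1, gaps + 1)
  ends <- c(gaps, length(t))
  pieces <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    idx <- starts[s]:ends[s]
    if (length(idx) < 4) next
    ts <- t[idx]
    grid <- seq(ts[1], ts[length(ts)], by = 1 / rate)
    ## keep segment endpoints exact
    if (grid[length(grid)] < ts[length(ts)])
      grid <- c(grid, ts[length(ts)])
    near <- findInterval(grid, ts, all.inside = TRUE)
    near <- ifelse(ts[near + 1] - grid < grid - ts[near], near + 1, near)
    interp <- function(v) {
      if (anyNA(v)) rep(NA_real_, length(grid)) else pracma::pchip(ts, v, grid)
    }
    pieces[[s]] <- data.frame(
      t_s = grid,
      x_px = interp(stream$x_px[idx]),
      y_px = interp(stream$y_px[idx]),
      x_deg = interp(stream$x_deg[idx]),
      y_deg = interp(stream$y_deg[idx]),
      pupil = stream$pupil[idx][near],
      confidence = stream$confidence[idx][near],
      valid = stream$valid[idx][near],
      label = stream$label[idx][near],
      stringsAsFactors = FALSE)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  out <- .as_stream(do.call(rbind, pieces))
  attr(out, "segments") <- length(pieces)
  out
}

#' Thin reader for ASC-style eye-tracker exports
#'
#' Converts a text export in the common ASC layout to the package's sample
#' contract: sample lines start with a numeric timestamp (ms) followed by
#' x, y gaze in screen pixels (top-left origin) and pupil size; event lines
#' \code{SBLINK}/\code{EBLINK}, \code{SSACC}/\code{ESACC},
#' \code{SFIX}/\code{EFIX} delimit labelled spans; \code{MSG} lines carry
#' trigger messages. Missing-data samples (dots or blank fields) become
#' invalid samples with no pupil. Native binary exports are out of scope.
#'
#' @param path file path of the ASC-style export.
#' @param geom optional \code{\link{screen_geometry}}; when given, pixel
#'   coordinates are re-centered (y flipped to point up) and degree columns
#'   filled.
#' @return list with \code{samples} (a \code{sample_stream}, times in
#'   seconds), \code{triggers} (msg, t_s) and \code{events} (type, onset,
#'   offset in seconds).
#' @export
read_asc <- function(path, geom = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  first <- sub("[[:space:]].*", "", lines)
  is_sample <- grepl("^[0-9]+(\\.[0-9]+)?$", first)

  parse_num <- function(v) suppressWarnings(as.numeric(v))
  samp <- strsplit(lines[is_sample], "[[:space:]]+")
  t_ms <- vapply(samp, function(f) parse_num(f[1]), numeric(1))
  xs <- vapply(samp, function(f) parse_num(f[2]), numeric(1))
  ys <- vapply(samp, function(f) parse_num(f[3]), numeric(1))
  pup <- vapply(samp, function(f) parse_num(f[4]), numeric(1))
  valid <- is.finite(xs) & is.finite(ys)

  ev_lines <- lines[!is_sample]
  tok <- strsplit(ev_lines, "[[:space:]]+")
  kind <- vapply(tok, `[`, character(1), 1)

  triggers <- data.frame(msg = character(0), t_s = numeric(0))
  msg_i <- which(kind == "MSG")
  if (length(msg_i)) {
    triggers <- data.frame(
      msg = vapply(tok[msg_i], function(f) paste(f[-(1:2)], collapse = " "),
                   character(1)),
      t_s = vapply(tok[msg_i], function(f) parse_num(f[2]), numeric(1)) / 1000)
  }

  nth_num <- function(f, k) {
    v <- parse_num(f)
    v <- v[is.finite(v)]
    if (length(v) >= k) v[k] else NA_real_
  }
  span <- function(s_kind, e_kind, type) {
    on <- vapply(tok[kind == s_kind], nth_num, numeric(1), k = 1)
    ## end lines repeat the start time, then the end time
    off <- vapply(tok[kind == e_kind], nth_num, numeric(1), k = 2)
    k <- min(length(on), length(off))
    if (k == 0) return(NULL)
    data.frame(type = type, onset = on[seq_len(k)] / 1000,
               offset = off[seq_len(k)] / 1000)
  }
  events <- rbind(span("SFIX", "EFIX", "fixation"),
                  span("SSACC", "ESACC", "saccade"),
                  span("SBLINK", "EBLINK", "blink"))

  label <- rep("none", sum(is_sample))
  t_s <- t_ms / 1000
  if (!is.null(events)) {
    ## ASC start/end stamps are inclusive of the end sample
    for (ty in c("fixation", "saccade", "blink")) {
      e <- events[events$type == ty, , drop = FALSE]
      for (i in seq_len(nrow(e)))
        label[t_s >= e$onset[i] & t_s <= e$offset[i]] <- ty
    }
  }
  if (!is.null(geom)) {
    xs <- xs - geom$width_px / 2
    ys <- geom$height_px / 2 - ys    # top-left origin to centered, y up
  }
  samples <- sample_stream(t_s = t_s, x_px = xs, y_px = ys,
                           pupil = ifelse(is.finite(pup) & pup > 0, pup,
                                          NA_real_),
                           confidence = NA_real_, valid = valid,
                           label = label, geom = geom)
  list(samples = samples, triggers = triggers,
       events = if (is.null(events)) .empty_events()[, 1:3] else events)
}
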