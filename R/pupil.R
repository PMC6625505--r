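#' Ellipse-based pupil area
#'
#' A = (1/4) * pi * l1 * l2 for the two reported pupil axes. With full axes
#' (diameters) this is the exact ellipse area; the same formula is applied
#' as the device convention regardless, and the axis convention of the
#' source tracker should be recorded alongside.
#'
#' @param l1,l2 pupil axes in device units (>= 0).
#' @return area in squared device units.
#' @export
diameter_to_area <- function(l1, l2) {
  if (any(l1 < 0, na.rm = TRUE) || any(l2 < 0, na.rm = TRUE))
    stop("negative pupil axis")
  pi / 4 * l1 * l2
}

#' Normalize a pupil trace to its pre-stimulus baseline
#'
#' Divides the pupil area trace by the median area over the
#' \code{baseline_window} seconds before stimulus onset. Blink-labelled
#' samples (plus their padding, already labelled upstream) are excluded from
#' both baseline and trace. Scale-invariant: multiplying the raw trace by
#' any positive constant leaves the result unchanged.
#'
#' @param t sample times, seconds.
#' @param area pupil areas, device units.
#' @param onset stimulus onset time, seconds.
#' @param baseline_window seconds before onset used as baseline, default 1.
#' @param exclude logical, samples to drop (e.g. blink-padded), default none.
#' @param min_baseline minimum number of valid baseline samples, default 10.
#' @return data frame \code{t_rel} (s from onset), \code{normalized} (area /
#'   median baseline area).
#' @export
normalize_to_baseline <- function(t, area, onset, baseline_window = 1,
                                  exclude = NULL, min_baseline = 10) {
  if (is.null(exclude)) exclude <- rep(FALSE, length(t))
  keep <- !exclude & is.finite(area)
  base <- keep & t >= onset - baseline_window & t < onset
  if (sum(base) < min_baseline)
    stop(sprintf("only %d valid baseline samples (need %d)",
                 sum(base), min_baseline))
  med <- stats::median(area[base])
  data.frame(t_rel = t[keep] - onset, normalized = area[keep] / med)
}

#' Per-luminance summary of normalized pupil responses
#'
#' For each trial, the mean normalized area inside \code{window} seconds
#' after the luminance change is taken; trial values are then aggregated by
#' winsorized means blocks -> subjects -> group per luminance level, with a
#' seeded bootstrap confidence interval.
#'
#' @param trials data frame with columns \code{luminance}, \code{block},
#'   \code{subject}, and per-trial normalized traces given as list-columns
#'   \code{t_rel}, \code{normalized} — or precomputed \code{response} values.
#' @param window two-element window in seconds after the change, default
#'   c(2, 3).
#' @param gamma winsorization fraction.
#' @param boot_seed seed of the bootstrap CI.
#' @return data frame: one row per luminance with \code{mean}, \code{ci_lo},
#'   \code{ci_hi}, \code{n_subjects}.
#' @export
luminance_summary <- function(trials, window = c(2, 3), gamma = 0.20,
                              boot_seed = 1L) {
  if (is.null(trials$response)) {
    trials$response <- vapply(seq_len(nrow(trials)), function(i) {
      tr <- trials$t_rel[[i]]; nr <- trials$normalized[[i]]
      mean(nr[tr >= window[1] & tr < window[2]])
    }, numeric(1))
  }
  lums <- sort(unique(trials$luminance))
  rows <- lapply(lums, function(L) {
    sub <- trials[trials$luminance == L, , drop = FALSE]
    h <- winsorized_hierarchy(sub, "response", c("block", "subject"), gamma,
                              ci = "bootstrap", boot_seed = boot_seed)
    data.frame(luminance = L, mean = h$mean, ci_lo = h$ci[1],
               ci_hi = h$ci[2], n_subjects = h$n)
  })
  do.call(rbind, rows)
}
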