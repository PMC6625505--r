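# Independent oracle implementations used to cross-check the package.
# These are written as plain, loop-based code and must stay independent of
# the implementations they verify.

# great-circle distance by the spherical law of cosines, treating elevation
# as latitude and azimuth as longitude
oracle_angular_distance <- function(az1, el1, az2, el2) {
  r <- pi / 180
  c_ang <- sin(el1 * r) * sin(el2 * r) +
    cos(el1 * r) * cos(el2 * r) * cos((az1 - az2) * r)
  acos(pmin(1, pmax(-1, c_ang))) / r
}

# explicit sort-and-replace winsorized mean
oracle_winsorized_mean <- function(x, gamma) {
  n <- length(x)
  k <- floor(gamma * n)
  s <- sort(x)
  if (k > 0) {
    s[1:k] <- s[k + 1]
    s[(n - k + 1):n] <- s[n - k]
  }
  mean(s)
}

# loop-based implementation of the velocity-threshold saccade classifier:
# 5-point velocity kernel, median-based sigma, elliptic criterion, run
# merging, minimum run length, dual-threshold boundary walk
oracle_saccade_bounds <- function(x, y, dt, lambda = 5, min_run = 3,
                                  merge_gap = 1, onset_lambda = 3,
                                  sigma_floor = 1e-6) {
  n <- length(x)
  vx <- numeric(n); vy <- numeric(n)
  for (i in 3:(n - 2)) {
    vx[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
    vy[i] <- (y[i + 2] + y[i + 1] - y[i - 1] - y[i - 2]) / (6 * dt)
  }
  vx[1] <- vx[2] <- vx[3]; vx[n] <- vx[n - 1] <- vx[n - 2]
  vy[1] <- vy[2] <- vy[3]; vy[n] <- vy[n - 1] <- vy[n - 2]
  sig <- function(v) sqrt(max(0, median(v^2) - median(v)^2))
  ex <- lambda * max(sig(vx), sigma_floor)
  ey <- lambda * max(sig(vy), sigma_floor)
  z <- (vx / ex)^2 + (vy / ey)^2
  flag <- z > 1
  # collect runs
  runs <- list()
  i <- 1
  while (i <= n) {
    if (flag[i]) {
      j <- i
      while (j < n && flag[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) == 0) return(matrix(numeric(0), ncol = 2))
  # merge runs separated by <= merge_gap
  merged <- list(runs[[1]])
  if (length(runs) > 1) {
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      if (r[1] - last[2] - 1 <= merge_gap)
        merged[[length(merged)]] <- c(last[1], r[2])
      else merged[[length(merged) + 1]] <- r
    }
  }
  merged <- Filter(function(r) r[2] - r[1] + 1 >= min_run, merged)
  if (length(merged) == 0) return(matrix(numeric(0), ncol = 2))
  # dual-threshold boundary walk
  z_on <- (min(onset_lambda, lambda) / lambda)^2
  prev_end <- 0
  out <- matrix(0, length(merged), 2)
  for (q in seq_along(merged)) {
    a <- merged[[q]][1]; b <- merged[[q]][2]
    while (a - 1 > prev_end && z[a - 1] > z_on) a <- a - 1
    nxt <- if (q < length(merged)) merged[[q + 1]][1] else n + 1
    while (b + 1 < nxt && z[b + 1] > z_on) b <- b + 1
    out[q, ] <- c(a, b)
    prev_end <- b
  }
  out
}

# convenience: uniform-rate stream with given degree coordinates
make_stream <- function(x, y, rate = 500, t0 = 0) {
  t <- t0 + (seq_along(x) - 1) / rate
  sample_stream(t_s = t, x_deg = x, y_deg = y, pupil = 100, confidence = 1)
}

# a fixation trace with one injected raised-cosine saccade
inject_saccade <- function(n, at, amplitude, direction = 0, rate = 500,
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  x <- rnorm(n, 0, noise_sd)
  y <- rnorm(n, 0, noise_sd)
  tr <- make_saccade_trace(amplitude, direction, rate)
  idx <- at + round(tr$t * rate)
  keep <- idx <= n
  x[idx[keep]] <- x[idx[keep]] + tr$dx[keep]
  y[idx[keep]] <- y[idx[keep]] + tr$dy[keep]
  last <- max(idx[keep])
  if (last < n) {
    x[(last + 1):n] <- x[(last + 1):n] + tr$dx[length(tr$dx)]
    y[(last + 1):n] <- y[(last + 1):n] + tr$dy[length(tr$dy)]
  }
  make_stream(x, y, rate)
}
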