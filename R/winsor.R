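#' Winsorized mean with Tukey-McLaughlin confidence interval
#'
#' Replaces the k = floor(gamma * n) smallest values by the (k+1)-th order
#' statistic and the k largest by the (n-k)-th, then averages. The default
#' gamma = 0.20 winsorizes 20% per tail. The confidence interval uses the
#' winsorized standard deviation with effective degrees of freedom
#' n - 2k - 1 and standard error s_w / ((1 - 2*gamma) * sqrt(n))
#' (Tukey-McLaughlin). Optionally a seeded percentile bootstrap interval is
#' computed instead.
#'
#' @param x numeric vector (NAs dropped).
#' @param gamma winsorization fraction per tail, in [0, 0.5).
#' @param ci_level confidence level (default 0.95).
#' @param ci one of "tm" (Tukey-McLaughlin, default), "bootstrap", "none".
#' @param n_boot bootstrap resamples (default 10000).
#' @param boot_seed integer seed for the bootstrap (required for
#'   reproducibility when \code{ci = "bootstrap"}).
#' @return list with \code{mean}, \code{winsorized_sd}, \code{ci} (length-2
#'   numeric), \code{n}, \code{gamma}.
#' @export
winsorized_mean <- function(x, gamma = 0.20, ci_level = 0.95,
                            ci = c("tm", "bootstrap", "none"),
                            n_boot = 10000, boot_seed = 1L) {
  ci <- match.arg(ci)
  if (gamma < 0 || gamma >= 0.5) stop("gamma must be in [0, 0.5)")
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1) stop("need at least one value")
  w <- .winsorize(x, gamma)
  m <- mean(w)
  s_w <- if (n > 1) stats::sd(w) else 0
  k <- floor(gamma * n)
  interval <- c(NA_real_, NA_real_)
  if (ci == "tm" && n > 1) {
    df <- n - 2 * k - 1
    if (df >= 1) {
      se <- s_w / ((1 - 2 * k / n) * sqrt(n))
      tq <- stats::qt(1 - (1 - ci_level) / 2, df)
      interval <- c(m - tq * se, m + tq * se)
    }
  } else if (ci == "bootstrap" && n > 1) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(boot_seed)
    bs <- replicate(n_boot, mean(.winsorize(sample(x, n, replace = TRUE), gamma)))
    interval <- unname(stats::quantile(bs, c((1 - ci_level) / 2,
                                             1 - (1 - ci_level) / 2)))
  } else if (ci != "none" && n == 1) {
    interval <- c(m, m)
  }
  list(mean = m, winsorized_sd = s_w, ci = interval, n = n, gamma = gamma)
}

.winsorize <- function(x, gamma) {
  n <- length(x)
  k <- floor(gamma * n)
  if (k == 0) return(x)
  s <- sort(x)
  lo <- s[k + 1]
  hi <- s[n - k]
  pmin(pmax(x, lo), hi)
}

## save/restore the global RNG state so seeded internals do not perturb the
## caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  } else assign(".Random.seed", old, envir = .GlobalEnv)
}

#' Winsorized aggregation over a grouping hierarchy
#'
#' Applies \code{\link{winsorized_mean}} successively along a hierarchy of
#' grouping columns (e.g. targets within blocks within subjects): at each
#' level the winsorized mean is taken over the units of that level, and the
#' resulting means feed the next level. The last call returns the group-level
#' winsorized mean with its confidence interval.
#'
#' @param df data frame holding one value per lowest-level unit.
#' @param value name of the value column.
#' @param levels character vector of grouping columns ordered from innermost
#'   aggregation to outermost; e.g. \code{c("block", "subject")} first
#'   averages values within each (subject, block), then blocks within each
#'   subject, then subjects into the group value.
#' @param gamma winsorization fraction per tail.
#' @param ci_level,ci,boot_seed passed to the final \code{winsorized_mean}.
#' @return list as from \code{\link{winsorized_mean}} for the group level,
#'   plus \code{per_unit}: data frame of the means one level below the group.
#' @export
winsorized_hierarchy <- function(df, value, levels, gamma = 0.20,
                                 ci_level = 0.95, ci = "tm", boot_seed = 1L) {
  stopifnot(value %in% names(df), all(levels %in% names(df)))
  cur <- df[, c(levels, value), drop = FALSE]
  for (i in seq_along(levels)) {
    keys <- levels[i:length(levels)]
    agg <- stats::aggregate(cur[[value]],
                            by = lapply(keys, function(k) cur[[k]]),
                            FUN = function(v) winsorized_mean(v, gamma, ci = "none")$mean)
    names(agg) <- c(keys, value)
    cur <- agg
  }
  res <- winsorized_mean(cur[[value]], gamma, ci_level = ci_level, ci = ci,
                         boot_seed = boot_seed)
  res$per_unit <- cur
  res
}
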