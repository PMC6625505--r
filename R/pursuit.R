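#' Configuration of the Bayesian hinge pursuit model
#'
#' Priors and sampler settings for \code{\link{fit_hinge}}. The model is a
#' restricted two-piece linear regression of gaze position along the target
#' direction on time: the first piece has slope 0 (fixation at intercept
#' alpha), the second rises with slope beta (tracking velocity) after the
#' hinge tau (pursuit onset). A logistic transfer of scale \code{k} blends
#' the two pieces so the likelihood is smooth.
#'
#' Default priors: alpha ~ Normal(0, 1 deg); tau ~ Normal(0.185 s, 0.300 s);
#' beta ~ Normal(0, 20 deg/s) truncated at 0; sigma ~ Normal(0, 5 deg)
#' truncated at 0.
#'
#' @param prior_alpha_sd SD of the intercept prior, degrees.
#' @param prior_tau_mean,prior_tau_sd hinge prior, seconds.
#' @param prior_beta_sd SD of the zero-truncated slope prior, deg/s.
#' @param prior_sigma_sd SD of the zero-truncated noise prior, degrees.
#' @param k logistic transfer scale, seconds (default 0.010).
#' @param sampler "mcmc" (JAGS, default) or "map_laplace" (fast
#'   mode-plus-curvature approximation).
#' @param chains,draws,adapt,burn MCMC settings (default 4 chains x 1000
#'   retained draws after 500 adaptation and 500 burn-in steps).
#' @param seed integer; fully determines the sampler output.
#' @return list of class \code{pursuit_config}.
#' @export
pursuit_config <- function(prior_alpha_sd = 1,
                           prior_tau_mean = 0.185, prior_tau_sd = 0.300,
                           prior_beta_sd = 20, prior_sigma_sd = 5,
                           k = 0.010,
                           sampler = c("mcmc", "map_laplace"),
                           chains = 4, draws = 1000, adapt = 500,
                           burn = 500, seed = 1L) {
  sampler <- match.arg(sampler)
  stopifnot(prior_alpha_sd > 0, prior_tau_sd > 0, prior_beta_sd > 0,
            prior_sigma_sd > 0, k > 0)
  structure(list(prior_alpha_sd = prior_alpha_sd,
                 prior_tau_mean = prior_tau_mean, prior_tau_sd = prior_tau_sd,
                 prior_beta_sd = prior_beta_sd,
                 prior_sigma_sd = prior_sigma_sd,
                 k = k, sampler = sampler, chains = chains, draws = draws,
                 adapt = adapt, burn = burn, seed = as.integer(seed)),
            class = "pursuit_config")
}

#' Prepare one step-ramp pursuit trial for model fitting
#'
#' Rotates gaze into the target-motion frame, restricts samples to the
#' window from motion onset up to the earlier of (a) the onset of the first
#' saccade exceeding 1 degree amplitude (a catch-up saccade) and (b) 600 ms
#' after motion onset, and drops blink-labelled samples. Times are
#' re-referenced to motion onset.
#'
#' @param stream labelled \code{sample_stream}.
#' @param saccades saccade event table on the same clock.
#' @param onset motion onset time, seconds (stream clock).
#' @param direction target motion direction, degrees.
#' @param target_speed target speed, deg/s (carried as metadata).
#' @param max_t fitting horizon after onset, default 0.600 s.
#' @param catchup_amp amplitude bound defining a catch-up saccade, default 1.
#' @param min_samples trials with fewer retained samples are flagged
#'   unusable, default 20.
#' @return list of class \code{pursuit_trial}: \code{t} (s from onset),
#'   \code{pos_along}, \code{pos_ortho} (deg), \code{target_speed},
#'   \code{direction}, \code{restriction_end}, \code{usable}.
#' @export
prepare_pursuit_trial <- function(stream, saccades, onset, direction,
                                  target_speed = NA_real_, max_t = 0.600,
                                  catchup_amp = 1, min_samples = 20) {
  restriction_end <- max_t
  if (!is.null(saccades) && nrow(saccades) > 0) {
    big <- saccades[saccades$amplitude > catchup_amp &
                    saccades$onset >= onset &
                    saccades$onset < onset + max_t, , drop = FALSE]
    if (nrow(big) > 0) restriction_end <- min(big$onset) - onset
  }
  sel <- stream$t_s >= onset & stream$t_s < onset + restriction_end &
    stream$label != "blink"
  rot <- rotate_to_target_direction(stream$x_deg[sel], stream$y_deg[sel],
                                    direction)
  structure(list(t = stream$t_s[sel] - onset,
                 pos_along = rot$along, pos_ortho = rot$ortho,
                 target_speed = target_speed, direction = direction,
                 restriction_end = restriction_end,
                 usable = sum(sel) >= min_samples),
            class = "pursuit_trial")
}

.hinge_mu <- function(t, alpha, tau, beta, k) {
  alpha + beta * (t - tau) / (1 + exp(-(t - tau) / k))
}

.jags_hinge_model <- "
model {
  for (i in 1:N) {
    w[i] <- 1 / (1 + exp(-(t[i] - tau) / k))
    mu[i] <- alpha + w[i] * beta * (t[i] - tau)
    y[i] ~ dnorm(mu[i], prec)
  }
  alpha ~ dnorm(0, 1 / (sd_alpha * sd_alpha))
  tau ~ dnorm(mu_tau, 1 / (sd_tau * sd_tau))
  beta ~ dnorm(0, 1 / (sd_beta * sd_beta)) T(0,)
  sigma ~ dnorm(0, 1 / (sd_sigma * sd_sigma)) T(0,)
  prec <- 1 / (sigma * sigma)
}"

## negative log posterior in the unconstrained parameterization
## (alpha, tau, log beta, log sigma), including the log-Jacobian
.hinge_nlp <- function(par, t, y, cfg) {
  alpha <- par[1]; tau <- par[2]
  beta <- exp(par[3]); sigma <- exp(par[4])
  mu <- .hinge_mu(t, alpha, tau, beta, cfg$k)
  ll <- sum(stats::dnorm(y, mu, sigma, log = TRUE))
  lp <- stats::dnorm(alpha, 0, cfg$prior_alpha_sd, log = TRUE) +
    stats::dnorm(tau, cfg$prior_tau_mean, cfg$prior_tau_sd, log = TRUE) +
    stats::dnorm(beta, 0, cfg$prior_beta_sd, log = TRUE) + par[3] +
    stats::dnorm(sigma, 0, cfg$prior_sigma_sd, log = TRUE) + par[4]
  -(ll + lp)
}

#' Fit the Bayesian hinge model to one pursuit trial
#'
#' Posterior inference for the smooth-pursuit onset (hinge) tau, tracking
#' velocity beta, pre-onset position alpha and residual noise sigma, under
#' the model mu(t) = alpha + w(t) * beta * (t - tau) with logistic weight
#' w(t) = 1 / (1 + exp(-(t - tau)/k)) and Normal(mu, sigma) likelihood.
#'
#' With \code{sampler = "mcmc"} the posterior is sampled with JAGS
#' (seeded; identical seeds give identical draws) and the split-chain
#' Gelman-Rubin statistic is computed per parameter; fits with any
#' R-hat >= 1.01 are flagged \code{converged = FALSE}. With
#' \code{sampler = "map_laplace"} the posterior mode is found in an
#' unconstrained parameterization and draws are taken from the Gaussian
#' (Laplace) approximation at the mode.
#'
#' @param trial a \code{\link{prepare_pursuit_trial}} result, or any list
#'   with numeric \code{t} and \code{pos_along}.
#' @param cfg a \code{\link{pursuit_config}}.
#' @return object of class \code{pursuit_fit}: posterior means
#'   \code{coefficients} (alpha, tau, beta, sigma), \code{draws} matrix,
#'   \code{rhat}, \code{converged}, \code{sampler}, \code{k}, and the data.
#' @export
fit_hinge <- function(trial, cfg = pursuit_config()) {
  t <- trial$t; y <- trial$pos_along
  stopifnot(length(t) == length(y))
  hyper <- list(N = length(t), t = t, y = y, k = cfg$k,
                sd_alpha = cfg$prior_alpha_sd,
                mu_tau = cfg$prior_tau_mean, sd_tau = cfg$prior_tau_sd,
                sd_beta = cfg$prior_beta_sd, sd_sigma = cfg$prior_sigma_sd)
  if (cfg$sampler == "mcmc") {
    inits <- lapply(seq_len(cfg$chains), function(ch) {
      list(alpha = 0, tau = cfg$prior_tau_mean, beta = 10, sigma = 1,
           .RNG.name = "base::Mersenne-Twister",
           .RNG.seed = cfg$seed * 1000L + ch)
    })
    model <- rjags::jags.model(textConnection(.jags_hinge_model),
                               data = hyper, inits = inits,
                               n.chains = cfg$chains, n.adapt = cfg$adapt,
                               quiet = TRUE)
    if (cfg$burn > 0) stats::update(model, cfg$burn, progress.bar = "none")
    samp <- rjags::coda.samples(model, c("alpha", "tau", "beta", "sigma"),
                                n.iter = cfg$draws, progress.bar = "none")
    draws <- do.call(rbind, lapply(samp, as.matrix))
    rhat <- tryCatch({
      g <- coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE)
      stats::setNames(g$psrf[, 1], rownames(g$psrf))
    }, error = function(e) stats::setNames(rep(NA_real_, 4),
                                           c("alpha", "beta", "sigma", "tau")))
    converged <- all(is.finite(rhat)) && all(rhat < 1.01)
  } else {
    start <- c(0, cfg$prior_tau_mean, log(10), log(1))
    opt <- stats::optim(start, .hinge_nlp, t = t, y = y, cfg = cfg,
                        method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500))
    ## Laplace draws in the unconstrained space, mapped back
    cov <- tryCatch(solve(opt$hessian), error = function(e) diag(1e-6, 4))
    cov <- (cov + t(cov)) / 2
    ev <- eigen(cov, symmetric = TRUE)
    ev$values <- pmax(ev$values, 1e-12)
    L <- ev$vectors %*% diag(sqrt(ev$values))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(cfg$seed)
    z <- matrix(stats::rnorm(4 * cfg$draws * cfg$chains), nrow = 4)
    u <- opt$par + L %*% z
    draws <- cbind(alpha = u[1, ], beta = exp(u[3, ]), sigma = exp(u[4, ]),
                   tau = u[2, ])
    rhat <- stats::setNames(rep(NA_real_, 4),
                            c("alpha", "beta", "sigma", "tau"))
    converged <- opt$convergence == 0
  }
  co <- colMeans(draws)[c("alpha", "tau", "beta", "sigma")]
  structure(list(coefficients = co, draws = draws, rhat = rhat,
                 converged = converged, sampler = cfg$sampler, k = cfg$k,
                 t = t, pos_along = y, cfg = cfg),
            class = "pursuit_fit")
}

#' @export
print.pursuit_fit <- function(x, ...) {
  cat("Bayesian hinge pursuit fit (", x$sampler, ")\n", sep = "")
  cat(sprintf("  onset tau: %.3f s   velocity beta: %.2f deg/s\n",
              x$coefficients["tau"], x$coefficients["beta"]))
  cat(sprintf("  intercept alpha: %.3f deg   noise sigma: %.3f deg\n",
              x$coefficients["alpha"], x$coefficients["sigma"]))
  if (!x$converged && any(is.finite(x$rhat)))
    cat(sprintf("  flagged: max R-hat %.3f >= 1.01 (inspect before aggregating)\n",
                max(x$rhat, na.rm = TRUE)))
  else if (!x$converged) cat("  flagged: fit did not converge\n")
  invisible(x)
}

#' @export
summary.pursuit_fit <- function(object, ...) {
  qs <- apply(object$draws, 2, stats::quantile,
              probs = c(0.025, 0.5, 0.975))
  out <- data.frame(mean = colMeans(object$draws),
                    sd = apply(object$draws, 2, stats::sd),
                    q2.5 = qs[1, ], median = qs[2, ], q97.5 = qs[3, ],
                    rhat = object$rhat[colnames(object$draws)])
  out
}

#' @export
coef.pursuit_fit <- function(object, ...) object$coefficients

#' @export
predict.pursuit_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$t else newdata$t
  co <- object$coefficients
  .hinge_mu(t, co["alpha"], co["tau"], co["beta"], object$k)
}

#' @export
residuals.pursuit_fit <- function(object, ...) {
  object$pos_along - predict(object)
}

#' @export
plot.pursuit_fit <- function(x, n_draws = 50, ...) {
  graphics::plot(x$t, x$pos_along, pch = 16, cex = 0.4,
                 xlab = "time from motion onset (s)",
                 ylab = "gaze along target direction (deg)", ...)
  idx <- seq(1, nrow(x$draws), length.out = min(n_draws, nrow(x$draws)))
  tt <- seq(min(x$t), max(x$t), length.out = 200)
  for (i in round(idx)) {
    d <- x$draws[i, ]
    graphics::lines(tt, .hinge_mu(tt, d["alpha"], d["tau"], d["beta"], x$k),
                    col = grDevices::adjustcolor("steelblue", 0.2))
  }
  co <- x$coefficients
  graphics::lines(tt, .hinge_mu(tt, co["alpha"], co["tau"], co["beta"], x$k),
                  col = "red", lwd = 2)
  graphics::abline(v = co["tau"], lty = 2, col = "red")
  invisible(x)
}

#' Count catch-up saccades inside a trial window
#'
#' Saccade events with onset in the half-open window [t0, t1) are counted;
#' initial reaction saccades are not distinguished from catch-up saccades.
#'
#' @param saccades saccade event table.
#' @param t0,t1 window bounds, seconds.
#' @return \code{count_catchup_saccades}: integer count.
#' @export
count_catchup_saccades <- function(saccades, t0, t1) {
  sum(saccades$onset >= t0 & saccades$onset < t1)
}

#' @rdname count_catchup_saccades
#' @return \code{catchup_amplitudes}: amplitudes (deg) of those saccades.
#' @export
catchup_amplitudes <- function(saccades, t0, t1) {
  saccades$amplitude[saccades$onset >= t0 & saccades$onset < t1]
}

#' Group-level pursuit summaries
#'
#' Winsorized means of per-trial posterior means, aggregated trials ->
#' blocks -> subjects -> group, separately for the onset tau and the
#' velocity beta.
#'
#' @param fits data frame with columns \code{tau_mean}, \code{beta_mean},
#'   \code{block}, \code{subject} (one row per usable trial).
#' @param gamma winsorization fraction.
#' @param ... passed to \code{\link{winsorized_hierarchy}}.
#' @return list with elements \code{tau} and \code{beta}, each as returned
#'   by \code{\link{winsorized_hierarchy}}.
#' @export
aggregate_pursuit <- function(fits, gamma = 0.20, ...) {
  list(tau = winsorized_hierarchy(fits, "tau_mean", c("block", "subject"),
                                  gamma, ...),
       beta = winsorized_hierarchy(fits, "beta_mean", c("block", "subject"),
                                   gamma, ...))
}
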