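# Steady and sinusoidal unsteady flow-speed series: generation and fitting.

#' Generate a (possibly sinusoidal) flow-speed series
#'
#' Produces the idealised set-point profile
#' `speed(t) = mean + amplitude * sin(2 pi t / period + phase)` plus optional
#' Gaussian measurement noise. `amplitude = 0` gives steady flow. Typical
#' protocols: swim-tunnel unsteady flow at mean speed with a 12 s wave period
#' and +/- 0.1 m s^-1 amplitude; tank unsteady flow at 0.50 +/- 0.05 m s^-1
#' with a 100 s period.
#'
#' @param mean Mean flow speed, m s^-1.
#' @param amplitude Wave amplitude, m s^-1 (>= 0).
#' @param period Wave period, seconds (> 0; ignored when amplitude is 0).
#' @param duration Series length, seconds.
#' @param dt Sampling interval, seconds; must be < period/4 for an unsteady
#'   profile so the wave is resolved.
#' @param phase Phase offset, radians.
#' @param noise_sd Gaussian measurement-noise s.d., m s^-1.
#' @param seed Optional RNG seed for the noise.
#' @return An object of class `flow_profile`: list with the generating
#'   parameters and a data frame `series` (`time_s`, `speed_mps`).
#' @examples
#' fp <- generate_flow(0.50, 0.05, 100, duration = 600, dt = 1)
#' range(fp$series$speed_mps)
#' @export
generate_flow <- function(mean, amplitude, period = NA_real_, duration,
                          dt = 1, phase = 0, noise_sd = 0, seed = NULL) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude > 0) {
    if (!is.finite(period) || period <= 0) stop("period must be > 0")
    if (dt >= period / 2) stop("dt must be below period/2 (aliasing)")
    if (dt >= period / 4) stop("dt must be below period/4 to resolve the wave")
  }
  t <- seq(0, duration, by = dt)
  speed <- if (amplitude > 0) {
    mean + amplitude * sin(2 * pi * t / period + phase)
  } else {
    rep(mean, length(t))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    speed <- speed + stats::rnorm(length(t), 0, noise_sd)
  }
  structure(list(mean_speed = mean, amplitude = amplitude, period = period,
                 phase = phase, duration = duration, dt = dt,
                 noise_sd = noise_sd,
                 series = data.frame(time_s = t, speed_mps = speed)),
            class = "flow_profile")
}

#' @export
print.flow_profile <- function(x, ...) {
  if (x$amplitude > 0) {
    cat(sprintf("Flow profile: %.3f +/- %.3f m/s, period %.1f s, %g s at dt=%g\n",
                x$mean_speed, x$amplitude, x$period, x$duration, x$dt))
  } else {
    cat(sprintf("Flow profile: steady %.3f m/s, %g s at dt=%g\n",
                x$mean_speed, x$duration, x$dt))
  }
  invisible(x)
}

# For a fixed period the sinusoid is linear in (mean, a, b) with
# speed = mean + a sin(wt) + b cos(wt); profile out the linear part and
# search the period on the residual sum of squares.
sinusoid_rss <- function(period, t, y) {
  w <- 2 * pi / period
  X <- cbind(1, sin(w * t), cos(w * t))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit a sinusoid to a measured flow-speed series
#'
#' Least-squares fit of `mean + amplitude * sin(2 pi t / period + phase)`.
#' The period is initialised at the discrete Fourier spectrum peak of the
#' mean-removed series; the three strongest non-zero frequencies seed a
#' golden-section refinement of the profiled residual sum of squares (for a
#' fixed period the remaining parameters are linear and solved exactly), and
#' the best of the multi-start wins. Returned amplitude is non-negative with
#' phase normalised to [0, 2 pi).
#'
#' @param speed Measured speeds, m s^-1 (regular sampling).
#' @param dt Sampling interval, seconds.
#' @param time Optional explicit sample times (overrides `dt` spacing).
#' @return Object of class `sinusoid_fit`: `mean`, `amplitude`, `period`,
#'   `phase`, `rss`, `converged`, `period_identifiable`. When the fitted
#'   amplitude is indistinguishable from noise the period is flagged
#'   unidentifiable.
#' @examples
#' fp <- generate_flow(0.5, 0.05, 100, duration = 600, dt = 1)
#' fit_sinusoid(fp$series$speed_mps, dt = 1)
#' @export
fit_sinusoid <- function(speed, dt, time = NULL) {
  y <- as.numeric(speed)
  t <- if (is.null(time)) (seq_along(y) - 1) * dt else as.numeric(time)
  n <- length(y)
  if (n < 8) stop("series too short to fit a sinusoid")

  centred <- y - mean(y)
  spec <- Mod(stats::fft(centred))[2:floor(n / 2)]
  freqs <- (seq_along(spec)) / (n * dt)  # cycles per second
  cand_idx <- order(spec, decreasing = TRUE)[seq_len(min(3, length(spec)))]
  cand_periods <- 1 / freqs[cand_idx]

  best <- NULL
  for (p0 in cand_periods) {
    # bracket one FFT bin either side of the candidate
    lo <- max(3 * dt, p0 * 0.5)
    hi <- min(n * dt * 2, p0 * 2)
    opt <- stats::optimise(sinusoid_rss, c(lo, hi), t = t, y = y, tol = 1e-9)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  period <- best$minimum
  w <- 2 * pi / period
  X <- cbind(1, sin(w * t), cos(w * t))
  cf <- stats::lm.fit(X, y)$coefficients
  amplitude <- sqrt(cf[2]^2 + cf[3]^2)
  phase <- atan2(cf[3], cf[2]) %% (2 * pi)

  # an amplitude below the residual noise level cannot pin down a period
  resid_sd <- sqrt(best$objective / max(1, n - 4))
  identifiable <- amplitude > resid_sd && amplitude > 1e-12
  structure(list(mean = unname(cf[1]), amplitude = unname(amplitude),
                 period = period, phase = unname(phase), rss = best$objective,
                 converged = TRUE, period_identifiable = identifiable),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("Sinusoid fit: %.4f +/- %.4f m/s, period %.2f s, phase %.3f rad\n",
              x$mean, x$amplitude, x$period, x$phase))
  if (!x$period_identifiable) {
    cat("  amplitude within noise: period not identifiable\n")
  }
  invisible(x)
}

#' @export
coef.sinusoid_fit <- function(object, ...) {
  c(mean = object$mean, amplitude = object$amplitude,
    period = object$period, phase = object$phase)
}

#' @export
predict.sinusoid_fit <- function(object, time, ...) {
  object$mean + object$amplitude *
    sin(2 * pi * time / object$period + object$phase)
}
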