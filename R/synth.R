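# Seeded generators for every input stream the pipeline consumes, each
# returning its ground truth alongside the data so downstream stages can be
# tested closed-loop.

#' Generate an intermittent-flow respirometry session
#'
#' Emulates the incremental-velocity protocol: an initial acclimation at
#' 0.15 m s^-1, then speeds from 0.30 to 0.90 m s^-1 in 0.15 m s^-1 steps,
#' with `replicates` cycles per speed. Each cycle is 5 min acclimation,
#' 15 min measurement, 10 min flush, sampled every 2 s. During measurement
#' phases oxygen declines linearly at the slope implied by inverting the MO2
#' equation for the configured true rate; flush phases restore saturation.
#' Gaussian sensor noise (in percent saturation) is added throughout.
#'
#' @param cfg A [respiro_config()].
#' @param true_mo2 True oxygen-consumption rate per speed, mg kg^-1 h^-1
#'   (default ramps 213 to 307 across the five speeds).
#' @param speeds Test speeds, m s^-1.
#' @param replicates Measurement cycles per speed.
#' @param noise_sd Sensor noise s.d., percent saturation.
#' @param sampling Sampling interval, seconds.
#' @param seed Optional RNG seed.
#' @return List with `trace` (`time_s`, `do_percent`, `phase`, `speed_mps`,
#'   `cycle`), `truth` (`speed`, `replicate`, `mo2_true`) and the config.
#' @export
gen_respiro_session <- function(cfg, true_mo2 = seq(213, 307, length.out = 5),
                                speeds = seq(0.30, 0.90, by = 0.15),
                                replicates = 3, noise_sd = 0.5,
                                sampling = 2, seed = NULL) {
  stopifnot(inherits(cfg, "respiro_config"),
            length(true_mo2) == length(speeds))
  if (!is.null(seed)) set.seed(seed)
  acclim_s <- 5 * 60; measure_s <- 15 * 60; flush_s <- 10 * 60

  segments <- list()
  truth <- list()
  t0 <- 0
  add_segment <- function(dur, phase, speed, do_fun) {
    tt <- seq(0, dur - sampling, by = sampling)
    seg <- data.frame(time_s = t0 + tt, do_percent = do_fun(tt),
                      phase = phase, speed_mps = speed,
                      cycle = length(segments) + 1L)
    segments[[length(segments) + 1L]] <<- seg
    t0 <<- t0 + dur
  }

  add_segment(2 * acclim_s, "acclimation", 0.15, function(tt) rep(100, length(tt)))
  for (i in seq_along(speeds)) {
    # % saturation decline per second implied by the true rate
    slope <- true_mo2[i] * cfg$body_mass * 100 /
      (cfg$do_max * cfg$chamber_volume * 3600)
    for (r in seq_len(replicates)) {
      add_segment(acclim_s, "acclimation", speeds[i],
                  function(tt) rep(100, length(tt)))
      add_segment(measure_s, "measure", speeds[i],
                  function(tt) 100 - slope * tt)
      add_segment(flush_s, "flush", speeds[i],
                  function(tt) pmin(100, 100 - slope * measure_s +
                                      (slope * measure_s / flush_s) * tt))
      truth[[length(truth) + 1L]] <-
        data.frame(speed = speeds[i], replicate = r, mo2_true = true_mo2[i])
    }
  }
  trace <- do.call(rbind, segments)
  if (noise_sd > 0) {
    trace$do_percent <- trace$do_percent +
      stats::rnorm(nrow(trace), 0, noise_sd)
  }
  list(trace = trace, truth = do.call(rbind, truth), cfg = cfg,
       noise_sd = noise_sd)
}

#' Recover per-speed MO2 from a (synthetic or measured) session trace
#'
#' Runs [compute_mo2()] on every measure phase of a session trace and
#' averages replicates per speed.
#'
#' @param trace Session trace as produced by [gen_respiro_session()] (or read
#'   from CSV with the same columns; a `cycle` column separates consecutive
#'   measure phases).
#' @param cfg A [respiro_config()].
#' @return List with `records` (one `mo2_record` per measure phase) and
#'   `summary` (per-speed mean, s.e.m., COT via [summarise_mo2()]).
#' @export
analyse_respiro_session <- function(trace, cfg) {
  meas <- trace[trace$phase == "measure", , drop = FALSE]
  if (nrow(meas) == 0) stop("trace contains no measure phase")
  key <- if ("cycle" %in% names(meas)) meas$cycle else
    cumsum(c(1, diff(meas$time_s) > 2 * stats::median(diff(meas$time_s))))
  parts <- split(meas, key)
  records <- do.call(rbind, lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    compute_mo2(p$time_s, p$do_percent, cfg, speed = p$speed_mps[1],
                replicate = i)
  }))
  # renumber replicates within speed
  records$replicate <- stats::ave(seq_len(nrow(records)), records$speed,
                                  FUN = seq_along)
  list(records = records, summary = summarise_mo2(records))
}

#' Generate a synthetic ECG burst
#'
#' A periodic PQRST-like template (sum of Gaussians: small P wave, sharp
#' biphasic QRS, broad T wave) at the requested heart rate, with additive
#' Gaussian noise and optional artifact events. The true R-peak times are
#' returned for closed-loop tests.
#'
#' @param hr True heart rate, beats min^-1 (30-150).
#' @param duration Burst length, seconds (nominal 7.5).
#' @param rate Sampling rate, Hz (nominal 200).
#' @param noise_sd Additive noise s.d. relative to unit R amplitude.
#' @param artifact_prob Probability that an artifact event is injected.
#' @param artifact Type of artifact: `"dropout"` zeroes a window covering
#'   `dropout_frac` of the burst, `"spike"` injects large random spikes.
#' @param dropout_frac Fraction of the burst zeroed by a dropout (1 = full).
#' @param seed Optional RNG seed.
#' @return List with `samples`, `rate`, `duration`, `true_peaks` (seconds)
#'   and `hr_true`.
#' @export
gen_ecg <- function(hr, duration = 7.5, rate = 200, noise_sd = 0,
                    artifact_prob = 0, artifact = c("dropout", "spike"),
                    dropout_frac = 1, seed = NULL) {
  if (hr < 30 || hr > 150) stop("hr must be within 30-150 beats min^-1")
  artifact <- match.arg(artifact)
  if (!is.null(seed)) set.seed(seed)
  n <- round(rate * duration)
  t <- (seq_len(n) - 1) / rate
  rr <- 60 / hr
  peaks <- seq(0.35, duration - 1e-9, by = rr)

  gauss <- function(centre, amp, width) {
    out <- numeric(n)
    for (p in centre) out <- out + amp * exp(-(t - p)^2 / (2 * width^2))
    out
  }
  samples <- gauss(peaks, 1, 0.012) +          # R
    gauss(peaks - 0.035, -0.18, 0.015) +       # Q
    gauss(peaks + 0.035, -0.22, 0.015) +       # S
    gauss(peaks - 0.18, 0.15, 0.035) +         # P
    gauss(peaks + 0.28, 0.30, 0.060)           # T
  if (noise_sd > 0) samples <- samples + stats::rnorm(n, 0, noise_sd)
  if (artifact_prob > 0 && stats::runif(1) < artifact_prob) {
    if (artifact == "dropout") {
      len <- max(1L, round(dropout_frac * n))
      start <- if (len >= n) 1L else sample.int(n - len, 1)
      samples[start:(start + len - 1L)] <- 0
    } else {
      idx <- sample.int(n, max(1L, round(0.01 * n)))
      samples[idx] <- samples[idx] + stats::rnorm(length(idx), 0, 5)
    }
  }
  list(samples = samples, rate = rate, duration = duration,
       true_peaks = peaks, hr_true = hr)
}

#' Generate a synthetic triaxial acceleration trace
#'
#' Gravity (1 g) on the heave axis plus a tail-beat sinusoid on the sway axis
#' whose rectified mean (2A/pi) equals the external acceleration predicted by
#' the swim-tunnel calibration at the given speed, plus sensor noise.
#' Tail-beat frequency increases with speed. Above 0.75 m s^-1, burst-glide
#' mode caps the target at the published drop-off level instead of the linear
#' trend, mirroring the transition away from steady aerobic swimming.
#'
#' @param speed Swimming speed, m s^-1 (>= 0).
#' @param duration Trace length, seconds.
#' @param rate Sampling rate, Hz (nominal 25).
#' @param condition Flow condition selecting the calibration line.
#' @param noise_sd Per-axis sensor noise s.d., g.
#' @param baseline_mg External acceleration at speed 0 (milli-g); default 0.
#' @param burst_glide Apply the burst-glide cap above 0.75 m s^-1?
#' @param registry Calibration registry.
#' @param seed Optional RNG seed.
#' @return List with `trace` (`time_s`, `ax_g`, `ay_g`, `az_g`), `rate`, and
#'   truth fields `target_ext_accel_mg`, `tailbeat_amp_g`, `tailbeat_hz`.
#' @export
gen_triaxial <- function(speed, duration = 60, rate = 25,
                         condition = c("steady", "unsteady"),
                         noise_sd = 0, baseline_mg = 0, burst_glide = TRUE,
                         registry = calibration_registry(), seed = NULL) {
  if (speed < 0) stop("speed must be >= 0")
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  target_mg <- if (speed <= 0) {
    baseline_mg
  } else if (burst_glide && speed > 0.75) {
    # published drop-off at the highest test speed
    if (condition == "steady") 14.30 else 15.31
  } else {
    as.numeric(predict(registry$accel_vs_speed[[condition]], speed))
  }
  amp_g <- (target_mg / 1000) * pi / 2  # rectified-sine mean = 2A/pi
  freq <- 1 + 2 * speed                 # tail-beat frequency grows with speed
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  n <- length(t)
  ax <- numeric(n)
  ay <- amp_g * sin(2 * pi * freq * t)
  az <- rep(1, n)
  if (noise_sd > 0) {
    ax <- ax + stats::rnorm(n, 0, noise_sd)
    ay <- ay + stats::rnorm(n, 0, noise_sd)
    az <- az + stats::rnorm(n, 0, noise_sd)
  }
  list(trace = data.frame(time_s = t, ax_g = ax, ay_g = ay, az_g = az),
       rate = rate, target_ext_accel_mg = target_mg,
       tailbeat_amp_g = amp_g, tailbeat_hz = freq)
}

#' Default sentinel-generator cell means and noise levels
#'
#' Day/night x treatment cell means per metric, calibrated to the published
#' free-swimming summaries, with residual and between-fish standard
#' deviations and feeding-peak amplitudes.
#'
#' @return Nested list keyed by metric.
#' @export
sentinel_defaults <- function() {
  list(
    hr_bpm = list(cells = c(steady.day = 71.10, steady.night = 60.50,
                            unsteady.day = 73.20, unsteady.night = 62.50),
                  residual_sd = 6, intercept_sd = 4, feeding_amp = 5),
    ext_accel_mg = list(cells = c(steady.day = 12.90, steady.night = 10.10,
                                  unsteady.day = 14.60, unsteady.night = 11.80),
                        residual_sd = 3, intercept_sd = 1.5, feeding_amp = 2),
    var_mg2 = list(cells = c(steady.day = 90, steady.night = 51,
                             unsteady.day = 128, unsteady.night = 86),
                   residual_sd = 25, intercept_sd = 12, feeding_amp = 15),
    odba_ms2 = list(cells = c(steady.day = 1.10, steady.night = 0.86,
                              unsteady.day = 1.13, unsteady.night = 0.88),
                    residual_sd = 0.15, intercept_sd = 0.07,
                    feeding_amp = 0.08)
  )
}

# feeding bumps at 09:00 and 16:00, mean-centred over the daytime hours so
# they shape the M-profile without shifting the day cell mean
feeding_bump <- function(hour_frac, amp, peaks = c(9, 16), width = 1,
                         day_hours = 6:17) {
  shape <- function(h) {
    rowSums(vapply(peaks, function(p) exp(-(h - p)^2 / (2 * width^2)),
                   numeric(length(h))))
  }
  grid <- seq(min(day_hours), max(day_hours) + 1, by = 1 / 60)
  amp * (shape(hour_frac) - mean(shape(grid)))
}

#' Generate a sentinel-fish telemetry series
#'
#' Per-fish hourly physiology emulating free-swimming sentinel fish in tanks:
#' a random intercept per fish (centred to mean zero across the cohort so the
#' realised cohort means reproduce the configured cells), treatment x
#' day/night cell means, feeding peaks at 09:00 and 16:00 (mean-centred over
#' the day window), and Gaussian residual noise, at fixed epochs across a
#' phase schedule of steady then unsteady flow.
#'
#' @param n_fish Number of sentinel fish (>= 2).
#' @param days_per_phase Days per flow phase (steady first, then unsteady).
#' @param epoch_min Epoch interval, minutes.
#' @param params Per-metric cells and noise levels ([sentinel_defaults()]).
#' @param start Start timestamp (POSIXct, timezone-naive local clock).
#' @param seed Optional RNG seed.
#' @param day_hours Daytime hours.
#' @return List with `data` (`fish_id`, `timestamp`, `treatment`, metric
#'   columns) and `truth` (the parameters plus realised intercepts).
#' @export
gen_sentinel <- function(n_fish = 10, days_per_phase = 14, epoch_min = 10,
                         params = sentinel_defaults(),
                         start = as.POSIXct("2024-03-04 00:00:00", tz = "UTC"),
                         seed = NULL, day_hours = 6:17) {
  if (n_fish < 2) stop("need at least 2 sentinel fish")
  if (!is.null(seed)) set.seed(seed)
  epochs_per_day <- 24 * 60 / epoch_min
  n_epoch <- 2 * days_per_phase * epochs_per_day
  offset_s <- (seq_len(n_epoch) - 1) * epoch_min * 60
  timestamp <- start + offset_s
  treatment <- ifelse(offset_s < days_per_phase * 86400, "steady", "unsteady")
  hour_frac <- (offset_s %% 86400) / 3600
  period <- label_period(floor(hour_frac), day_hours = day_hours)

  metrics <- names(params)
  intercepts <- lapply(params, function(p) {
    b <- stats::rnorm(n_fish, 0, p$intercept_sd)
    b - mean(b)  # centre so cohort means match the configured cells
  })

  rows <- lapply(seq_len(n_fish), function(f) {
    df <- data.frame(fish_id = sprintf("fish%02d", f), timestamp = timestamp,
                     treatment = treatment, stringsAsFactors = FALSE)
    for (m in metrics) {
      p <- params[[m]]
      cell <- p$cells[paste(treatment, period, sep = ".")]
      bump <- ifelse(period == "day",
                     feeding_bump(hour_frac, p$feeding_amp,
                                  day_hours = day_hours), 0)
      df[[m]] <- as.numeric(cell) + intercepts[[m]][f] + bump +
        stats::rnorm(n_epoch, 0, p$residual_sd)
    }
    df
  })
  list(data = do.call(rbind, rows),
       truth = list(params = params, intercepts = intercepts,
                    n_fish = n_fish, days_per_phase = days_per_phase,
                    epoch_min = epoch_min, day_hours = day_hours))
}

#' Generate an acoustic-transmitter detection stream
#'
#' Detection epochs with gaps uniform on [30, 50] s; each detection carries
#' the mean ODBA of the underlying series since the previous epoch.
#'
#' @param time_s Sample times of the underlying ODBA series, seconds.
#' @param odba_ms2 ODBA values aligned with `time_s`.
#' @param gap_range Detection-interval range, seconds.
#' @param seed Optional RNG seed.
#' @return Data frame `timestamp_s`, `odba_ms2`.
#' @export
gen_transmitter_stream <- function(time_s, odba_ms2, gap_range = c(30, 50),
                                   seed = NULL) {
  if (max(time_s) - min(time_s) <= gap_range[2]) {
    stop("series must be longer than the maximum detection gap")
  }
  if (!is.null(seed)) set.seed(seed)
  detections <- list()
  prev <- min(time_s)
  t <- prev + stats::runif(1, gap_range[1], gap_range[2])
  while (t <= max(time_s)) {
    idx <- time_s > prev & time_s <= t
    detections[[length(detections) + 1L]] <-
      data.frame(timestamp_s = t, odba_ms2 = mean(odba_ms2[idx]))
    prev <- t
    t <- t + stats::runif(1, gap_range[1], gap_range[2])
  }
  do.call(rbind, detections)
}
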