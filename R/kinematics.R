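# Triaxial accelerometry: static/dynamic separation, external acceleration
# (Euclidean norm, milli-g), VAR, and ODBA (L1 norm, m s^-2).

G_MS2 <- 9.81  # standard gravity used to convert g to m s^-2

# centered running mean with shrinking windows at the edges, so that
# static + dynamic always reconstructs the raw signal exactly
running_mean <- function(x, halfwidth) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - halfwidth, 1L)
  hi <- pmin(seq_len(n) + halfwidth, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Separate static (gravitational) and dynamic acceleration
#'
#' The static component per axis is a centered running mean over `window`
#' seconds; the dynamic component is the raw signal minus the static one, so
#' the two always sum back to the raw trace. The default 3 s window is much
#' longer than a tail-beat period (~0.3-1 s) and much shorter than posture
#' changes, so gravity and slow orientation drift stay in the static part
#' while locomotor oscillations pass to the dynamic part.
#'
#' @param ax,ay,az Surge, sway and heave acceleration in g (equal lengths).
#' @param rate Sampling rate, Hz (nominal 25).
#' @param window Running-mean window, seconds; must be >= 2 samples.
#' @return List with data frames `static` and `dynamic`, each with columns
#'   `ax`, `ay`, `az`.
#' @export
split_static_dynamic <- function(ax, ay, az, rate = 25, window = 3) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n) stop("axes must have equal length")
  if (rate <= 0) stop("rate must be > 0")
  if (window < 2 / rate) stop("window must cover at least 2 samples")
  if (n < window * rate) stop("trace is shorter than the smoothing window")
  hw <- max(1L, floor(window * rate / 2))
  static <- data.frame(ax = running_mean(ax, hw),
                       ay = running_mean(ay, hw),
                       az = running_mean(az, hw))
  dynamic <- data.frame(ax = ax - static$ax, ay = ay - static$ay,
                        az = az - static$az)
  list(static = static, dynamic = dynamic)
}

#' External acceleration (vectorial dynamic body acceleration, milli-g)
#'
#' The logger-style activity metric: the mean over the interval of the
#' Euclidean norm of the instantaneous dynamic acceleration vector,
#' sqrt(dx^2 + dy^2 + dz^2), expressed in milli-g.
#'
#' @param dynamic Data frame with dynamic `ax`, `ay`, `az` in g.
#' @return Mean external acceleration in m*g* (milli-g).
#' @export
external_acceleration <- function(dynamic) {
  if (nrow(dynamic) == 0) stop("empty interval")
  norm_g <- sqrt(dynamic$ax^2 + dynamic$ay^2 + dynamic$az^2)
  mean(norm_g) * 1000
}

#' Overall dynamic body acceleration (ODBA, m s^-2)
#'
#' The transmitter-style activity metric: the mean over the interval of the
#' summed absolute dynamic accelerations |dx| + |dy| + |dz| (L1 norm),
#' converted from g to m s^-2 with g = 9.81 m s^-2.
#'
#' @param dynamic Data frame with dynamic `ax`, `ay`, `az` in g.
#' @return ODBA in m s^-2.
#' @export
odba <- function(dynamic) {
  if (nrow(dynamic) == 0) stop("empty interval")
  l1_g <- abs(dynamic$ax) + abs(dynamic$ay) + abs(dynamic$az)
  mean(l1_g) * G_MS2
}

#' Variance of external acceleration (VAR, milli-g squared)
#'
#' Sample variance of external-acceleration values within an aggregation
#' interval. Elevated VAR distinguishes erratic burst-coast swimming from the
#' steady tail-beat regime that keeps VAR low.
#'
#' @param ext_accel_samples External-acceleration samples in milli-g
#'   (at least two).
#' @return Sample variance in m*g*^2.
#' @export
var_acceleration <- function(ext_accel_samples) {
  if (length(ext_accel_samples) < 2) stop("need at least 2 samples")
  stats::var(ext_accel_samples)
}

#' Flag erratic (burst-coast) swimming from VAR
#'
#' VAR above the threshold (default 222 m*g*^2, the published burst-coast /
#' distress indicator for similarly sized salmonids) flags the interval as
#' erratic; the comparison is strict.
#'
#' @param var_value VAR in m*g*^2 (>= 0).
#' @param threshold Threshold in m*g*^2.
#' @return Logical flag.
#' @export
flag_erratic <- function(var_value, threshold = 222) {
  if (any(var_value < 0)) stop("VAR must be >= 0")
  var_value > threshold
}

#' Aggregate a triaxial trace into activity records
#'
#' Splits static/dynamic, then computes external acceleration, VAR (variance
#' of per-second external acceleration within each epoch) and ODBA over
#' consecutive epochs of `epoch` seconds.
#'
#' @param time Sample times, seconds.
#' @param ax,ay,az Raw acceleration in g.
#' @param rate Sampling rate, Hz.
#' @param window Static-removal window, seconds.
#' @param epoch Aggregation epoch, seconds.
#' @return Data frame `time_s, ext_accel_mg, var_mg2, odba_ms2` (one row per
#'   complete epoch).
#' @export
aggregate_activity <- function(time, ax, ay, az, rate = 25, window = 3,
                               epoch = 60) {
  sd_split <- split_static_dynamic(ax, ay, az, rate = rate, window = window)
  dyn <- sd_split$dynamic
  t0 <- time[1]
  bin <- floor((time - t0) / epoch)
  complete <- bin < max(bin)  # drop the trailing partial epoch
  if (!any(complete)) stop("trace shorter than one epoch")
  out <- lapply(unique(bin[complete]), function(b) {
    idx <- which(bin == b)
    d <- dyn[idx, , drop = FALSE]
    # per-second external acceleration samples within the epoch, for VAR
    sec <- floor((time[idx] - t0))
    ea_sec <- vapply(split(seq_along(idx), sec), function(j) {
      external_acceleration(d[j, , drop = FALSE])
    }, numeric(1))
    data.frame(time_s = t0 + b * epoch,
               ext_accel_mg = external_acceleration(d),
               var_mg2 = if (length(ea_sec) > 1) stats::var(ea_sec)
                         else NA_real_,
               odba_ms2 = odba(d))
  })
  do.call(rbind, out)
}
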