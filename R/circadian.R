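# Sentinel-fish telemetry: day/night labelling, hourly aggregation, and the
# random-intercept mixed model for repeated measurements.

#' Label a timestamp as day or night
#'
#' Hour-of-day bins: hours 6-17 (covering 06:00:00-17:59:59) are daytime,
#' hours 18-23 and 0-5 are night-time. Treating the published clock ranges as
#' inclusive hour bins makes the partition of the 24 h exhaustive with no
#' gaps. The day window is configurable.
#'
#' @param timestamp POSIXct timestamp(s), or integer hour(s) of day 0-23.
#' @param day_hours Integer hours counted as daytime.
#' @return Character vector, `"day"` or `"night"`.
#' @examples
#' label_period(as.POSIXct("2024-01-01 09:00:00", tz = "UTC"))
#' @export
label_period <- function(timestamp, day_hours = 6:17) {
  hour <- if (inherits(timestamp, "POSIXt")) {
    as.integer(format(timestamp, "%H"))
  } else {
    h <- as.integer(timestamp)
    if (any(h < 0 | h > 23)) stop("hours must be in 0..23")
    h
  }
  ifelse(hour %in% day_hours, "day", "night")
}

#' Hourly aggregation of sentinel telemetry
#'
#' Arithmetic means per fish x hour-of-day x treatment for each metric, plus
#' the group-level mean and s.e.m. across fish for each hour x treatment
#' cell. Empty cells are dropped.
#'
#' @param data Data frame with columns `fish_id`, `timestamp`, `treatment`
#'   and one or more metric columns (`hr_bpm`, `ext_accel_mg`, `var_mg2`,
#'   `odba_ms2`).
#' @param metrics Metric columns to aggregate (defaults to those present).
#' @return List with `per_fish` (fish x hour x treatment means) and `group`
#'   (hour x treatment mean and s.e.m. across fish).
#' @export
hourly_aggregate <- function(data, metrics = NULL) {
  stopifnot(all(c("fish_id", "timestamp", "treatment") %in% names(data)))
  if (is.null(metrics)) {
    metrics <- intersect(c("hr_bpm", "ext_accel_mg", "var_mg2", "odba_ms2"),
                         names(data))
  }
  hour <- if (inherits(data$timestamp, "POSIXt")) {
    as.integer(format(data$timestamp, "%H"))
  } else as.integer(data$timestamp) %% 24L

  per_fish <- stats::aggregate(data[metrics],
                               by = list(fish_id = data$fish_id, hour = hour,
                                         treatment = data$treatment),
                               FUN = mean, na.rm = TRUE)
  sem <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }
  grp_mean <- stats::aggregate(per_fish[metrics],
                               by = list(hour = per_fish$hour,
                                         treatment = per_fish$treatment),
                               FUN = mean, na.rm = TRUE)
  grp_sem <- stats::aggregate(per_fish[metrics],
                              by = list(hour = per_fish$hour,
                                        treatment = per_fish$treatment),
                              FUN = sem)
  names(grp_sem)[-(1:2)] <- paste0(metrics, "_sem")
  list(per_fish = per_fish, group = merge(grp_mean, grp_sem))
}

#' Day/night summary table
#'
#' 2 x 2 (period x treatment) mean and s.e.m. per metric, computed from
#' per-fish period means (so each fish contributes one value per cell and the
#' s.e.m. reflects between-fish variability).
#'
#' @param data As for [hourly_aggregate()].
#' @param metrics Metric columns to summarise.
#' @param day_hours Daytime hours passed to [label_period()].
#' @return Data frame with columns `treatment`, `period`, then
#'   `<metric>`/`<metric>_sem` pairs.
#' @export
day_night_summary <- function(data, metrics = NULL, day_hours = 6:17) {
  stopifnot(all(c("fish_id", "timestamp", "treatment") %in% names(data)))
  if (is.null(metrics)) {
    metrics <- intersect(c("hr_bpm", "ext_accel_mg", "var_mg2", "odba_ms2"),
                         names(data))
  }
  period <- label_period(data$timestamp, day_hours = day_hours)
  per_fish <- stats::aggregate(data[metrics],
                               by = list(fish_id = data$fish_id,
                                         treatment = data$treatment,
                                         period = period),
                               FUN = mean, na.rm = TRUE)
  sem <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }
  m <- stats::aggregate(per_fish[metrics],
                        by = list(treatment = per_fish$treatment,
                                  period = per_fish$period),
                        FUN = mean, na.rm = TRUE)
  s <- stats::aggregate(per_fish[metrics],
                        by = list(treatment = per_fish$treatment,
                                  period = per_fish$period),
                        FUN = sem)
  names(s)[-(1:2)] <- paste0(metrics, "_sem")
  merge(m, s)
}

#' Random-intercept mixed model for sentinel telemetry
#'
#' Fits `response ~ Treatment + Period_of_Day + (1 | fish_id)` by REML, the
#' standard repeated-measures structure for telemetry time series: fixed
#' effects for flow condition and day/night period, a random intercept per
#' fish absorbing between-individual level differences, and independent
#' Gaussian residuals. The Treatment x Period interaction is pre-tested by a
#' maximum-likelihood likelihood-ratio test and retained only when
#' significant at `alpha`; the reported model is then refitted by REML.
#' Wald tests (Satterthwaite degrees of freedom) are reported for the fixed
#' effects.
#'
#' @param data Data frame with `fish_id`, `timestamp`, `treatment` and the
#'   response column; a `period` column is derived from `timestamp` if
#'   absent.
#' @param response One of `"hr_bpm"`, `"ext_accel_mg"`, `"var_mg2"`,
#'   `"odba_ms2"` (or any numeric column).
#' @param alpha Significance level for the interaction pre-test.
#' @param day_hours Daytime hours for [label_period()].
#' @return Object of class `activity_lmm`: the `lmerTest` fit plus the
#'   coefficient table, variance components, interaction decision, and a
#'   singular-fit flag.
#' @export
fit_activity_lmm <- function(data, response = "hr_bpm", alpha = 0.05,
                             day_hours = 6:17) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (length(unique(data$fish_id)) < 2) {
    stop("random intercept unidentifiable with a single fish")
  }
  if (!"period" %in% names(data)) {
    data$period <- label_period(data$timestamp, day_hours = day_hours)
  }
  if (length(unique(data$treatment)) < 2 || length(unique(data$period)) < 2) {
    stop("both treatments and both periods must be represented")
  }
  df <- data.frame(y = data[[response]],
                   treatment = factor(data$treatment,
                                      levels = c("steady", "unsteady")),
                   period = factor(data$period, levels = c("night", "day")),
                   fish_id = factor(data$fish_id))
  df <- df[is.finite(df$y), ]

  # interaction pre-test under ML
  m0 <- lme4::lmer(y ~ treatment + period + (1 | fish_id), data = df,
                   REML = FALSE)
  m1 <- lme4::lmer(y ~ treatment * period + (1 | fish_id), data = df,
                   REML = FALSE)
  lrt_p <- stats::anova(m0, m1)[2, "Pr(>Chisq)"]
  use_interaction <- is.finite(lrt_p) && lrt_p < alpha

  form <- if (use_interaction) {
    y ~ treatment * period + (1 | fish_id)
  } else {
    y ~ treatment + period + (1 | fish_id)
  }
  fit <- suppressMessages(lmerTest::lmer(form, data = df, REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular fit: random-intercept variance estimated at zero")
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  coefs <- stats::coef(summary(fit))
  structure(list(fit = fit, response = response,
                 coefficients = coefs,
                 interaction_included = use_interaction,
                 interaction_p = lrt_p,
                 random_intercept_sd = vc$sdcor[vc$grp == "fish_id"],
                 residual_sd = vc$sdcor[vc$grp == "Residual"],
                 n_fish = length(unique(df$fish_id)),
                 n_obs = nrow(df), singular = singular),
            class = "activity_lmm")
}

#' @export
print.activity_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept LMM for %s (%d fish, %d obs)\n",
              x$response, x$n_fish, x$n_obs))
  cat(sprintf("  %s ~ treatment %s period + (1 | fish_id), REML\n",
              x$response, if (x$interaction_included) "*" else "+"))
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("  random-intercept sd %.3f, residual sd %.3f\n",
              x$random_intercept_sd, x$residual_sd))
  if (x$singular) cat("  (singular fit)\n")
  invisible(x)
}

#' @export
coef.activity_lmm <- function(object, ...) {
  object$coefficients[, "Estimate"]
}

#' @export
summary.activity_lmm <- function(object, ...) summary(object$fit, ...)

#' Fixed effect with standard error and p-value
#'
#' Convenience accessor for one fixed-effect row of an [fit_activity_lmm()]
#' fit.
#'
#' @param x An `activity_lmm`.
#' @param term Row name, e.g. `"periodday"` or `"treatmentunsteady"`.
#' @return Named numeric: `estimate`, `se`, `p`.
#' @export
fixed_effect <- function(x, term) {
  stopifnot(inherits(x, "activity_lmm"))
  if (!term %in% rownames(x$coefficients)) {
    stop("no fixed effect named ", term)
  }
  row <- x$coefficients[term, ]
  c(estimate = unname(row["Estimate"]), se = unname(row["Std. Error"]),
    p = unname(row["Pr(>|t|)"]))
}
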