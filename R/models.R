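# Linear calibration models linking swimming speed, activity metrics and
# oxygen consumption, and their transfer to free-swimming predictions.

#' Construct a calibration model
#'
#' A fitted (or published) straight line y = slope * x + intercept together
#' with the metadata needed to apply it safely: which predictor convention x
#' uses, the response unit, the flow condition it was calibrated under, and
#' the speed range it covers (predictions outside it are flagged as
#' extrapolation).
#'
#' Predictor conventions:
#' \describe{
#'   \item{`speed_mps`}{swimming speed in m s^-1}
#'   \item{`speed_step_index`}{swimming speed expressed as a count of
#'     0.15 m s^-1 protocol steps, i.e. speed / 0.15}
#'   \item{`ext_accel_mg`}{external acceleration in milli-g}
#'   \item{`odba_ms2`}{ODBA in m s^-2}
#' }
#'
#' @param slope,intercept Line coefficients.
#' @param r_squared Coefficient of determination in [0, 1].
#' @param x_convention One of the conventions above.
#' @param y_unit One of `"mg"` (milli-g), `"ms2"` (m s^-2),
#'   `"mgkg h"` (mg kg^-1 h^-1).
#' @param flow_condition `"steady"` or `"unsteady"`.
#' @param speed_range Calibrated speed range (min, max) in m s^-1, or `NULL`.
#' @param description Free-text provenance note.
#' @return Object of class `calibration_model`.
#' @export
calibration_model <- function(slope, intercept, r_squared = NA_real_,
                              x_convention = c("speed_mps", "speed_step_index",
                                               "ext_accel_mg", "odba_ms2"),
                              y_unit = c("mg", "ms2", "mgkg h"),
                              flow_condition = c("steady", "unsteady"),
                              speed_range = NULL, description = "") {
  x_convention <- match.arg(x_convention)
  y_unit <- match.arg(y_unit)
  flow_condition <- match.arg(flow_condition)
  if (is.finite(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]")
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r_squared,
                 x_convention = x_convention, y_unit = y_unit,
                 flow_condition = flow_condition, speed_range = speed_range,
                 description = description),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration (%s flow): y = %.4g x %+.4g   [x: %s, y: %s]\n",
              x$flow_condition, x$slope, x$intercept, x$x_convention,
              x$y_unit))
  if (is.finite(x$r_squared)) cat(sprintf("  R^2 = %.2f\n", x$r_squared))
  if (!is.null(x$speed_range)) {
    cat(sprintf("  calibrated over %.2f-%.2f m/s\n",
                x$speed_range[1], x$speed_range[2]))
  }
  invisible(x)
}

#' @export
coef.calibration_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Ordinary least-squares line fit
#'
#' Fits y = slope x + intercept by OLS; R^2 is the squared Pearson
#' correlation of x and y (identical to the regression R^2 for a straight
#' line).
#'
#' @param x,y Numeric vectors, >= 3 points, x not constant.
#' @param ... Metadata passed to [calibration_model()] (`x_convention`,
#'   `y_unit`, `flow_condition`, `speed_range`, `description`).
#' @return A `calibration_model`.
#' @examples
#' fit_line(1:5, 2 * (1:5) + 1)
#' @export
fit_line <- function(x, y, ...) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("constant x: line is unidentifiable")
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)^2
  calibration_model(slope = unname(fit$coefficients[2]),
                    intercept = unname(fit$coefficients[1]),
                    r_squared = r2, ...)
}

#' Predict from a calibration model
#'
#' Applies y = slope x + intercept after converting the raw predictor to the
#' model's x-convention: speeds in m s^-1 are divided by 0.15 for
#' `speed_step_index` models; activity-metric predictors are used as-is.
#' Speed predictions outside the calibrated range carry an `extrapolated`
#' attribute.
#'
#' @param object A `calibration_model`.
#' @param x_raw Predictor value(s): swimming speed in m s^-1 for speed-based
#'   models, or the activity metric in the model's x unit.
#' @param step_size Protocol step size used by the step-index convention
#'   (m s^-1).
#' @param ... Unused.
#' @return Predicted value(s) with attribute `extrapolated` (logical).
#' @examples
#' reg <- calibration_registry()
#' predict(reg$accel_vs_speed$steady, 0.50)  # 13.04 milli-g
#' @export
predict.calibration_model <- function(object, x_raw, step_size = 0.15, ...) {
  x <- switch(object$x_convention,
              speed_mps = x_raw,
              speed_step_index = x_raw / step_size,
              ext_accel_mg = x_raw,
              odba_ms2 = x_raw)
  y <- object$slope * x + object$intercept
  extrap <- rep(FALSE, length(y))
  if (!is.null(object$speed_range) &&
      object$x_convention %in% c("speed_mps", "speed_step_index")) {
    extrap <- x_raw < object$speed_range[1] | x_raw > object$speed_range[2]
  }
  attr(y, "extrapolated") <- extrap
  y
}

#' Chain two calibrations to predict oxygen consumption from speed
#'
#' Composes a speed-to-activity model with an activity-to-MO2 model:
#' speed -> predicted activity metric -> predicted MO2. The units must chain:
#' the first model's response unit has to match the second model's predictor
#' convention (milli-g external acceleration feeding an acceleration-MO2
#' model, or m s^-2 ODBA feeding an ODBA-MO2 model).
#'
#' @param speed_model `calibration_model` mapping speed to an activity metric.
#' @param mo2_model `calibration_model` mapping that metric to MO2.
#' @param speed Swimming speed, m s^-1.
#' @return List with `speed`, `activity` (intermediate prediction), `mo2`
#'   (mg kg^-1 h^-1) and `extrapolated`.
#' @examples
#' reg <- calibration_registry()
#' chain_predict_mo2(reg$accel_vs_speed$steady, reg$mo2_vs_accel$steady, 0.5)
#' @export
chain_predict_mo2 <- function(speed_model, mo2_model, speed) {
  link <- c(mg = "ext_accel_mg", ms2 = "odba_ms2")[[speed_model$y_unit]]
  if (is.null(link) || mo2_model$x_convention != link) {
    stop("unit mismatch: ", speed_model$y_unit,
         " output cannot feed a ", mo2_model$x_convention, " predictor")
  }
  if (mo2_model$y_unit != "mgkg h") stop("mo2_model must predict mg kg^-1 h^-1")
  activity <- predict(speed_model, speed)
  mo2 <- predict(mo2_model, as.numeric(activity))
  list(speed = speed, activity = as.numeric(activity), mo2 = as.numeric(mo2),
       extrapolated = attr(activity, "extrapolated"))
}

#' Published swim-tunnel calibration registry
#'
#' The eight straight-line calibrations from the swim-tunnel respirometry
#' study of post-smolt Chinook salmon, as constants: external acceleration
#' and ODBA versus swimming speed, and oxygen consumption versus each
#' activity metric, under steady and unsteady flow. Acceleration-speed lines
#' take speed in m s^-1 and were calibrated over 0.30-0.75 m s^-1 (above
#' which burst-glide swimming breaks the linear trend); ODBA-speed lines take
#' speed as a 0.15 m s^-1 step index — each entry carries its own convention,
#' which is the only reading that reproduces the published free-swimming
#' predictions (13.04 / 13.74 milli-g and 1.33 m s^-2 at 0.50 m s^-1).
#'
#' @return Nested list `registry[[model]][[flow_condition]]` with models
#'   `accel_vs_speed`, `odba_vs_speed`, `mo2_vs_accel`, `mo2_vs_odba`.
#' @examples
#' reg <- calibration_registry()
#' predict(reg$odba_vs_speed$unsteady, 0.50)  # 1.33 m s^-2
#' @export
calibration_registry <- function() {
  list(
    accel_vs_speed = list(
      steady = calibration_model(18.31, 3.88, 0.99, "speed_mps", "mg",
                                 "steady", c(0.30, 0.75),
                                 "external acceleration vs speed, swim tunnel"),
      unsteady = calibration_model(13.52, 6.99, 0.95, "speed_mps", "mg",
                                   "unsteady", c(0.30, 0.75),
                                   "external acceleration vs speed, swim tunnel")
    ),
    odba_vs_speed = list(
      steady = calibration_model(0.16, 0.54, 0.94, "speed_step_index", "ms2",
                                 "steady", c(0.30, 0.90),
                                 "ODBA vs speed-step index, swim tunnel"),
      unsteady = calibration_model(0.24, 0.53, 0.92, "speed_step_index", "ms2",
                                   "unsteady", c(0.30, 0.90),
                                   "ODBA vs speed-step index, swim tunnel")
    ),
    mo2_vs_accel = list(
      steady = calibration_model(4.17, 171.34, 0.56, "ext_accel_mg", "mgkg h",
                                 "steady", NULL,
                                 "MO2 vs external acceleration, swim tunnel"),
      unsteady = calibration_model(6.85, 150.98, 0.79, "ext_accel_mg",
                                   "mgkg h", "unsteady", NULL,
                                   "MO2 vs external acceleration, swim tunnel")
    ),
    mo2_vs_odba = list(
      steady = calibration_model(78.83, 151.99, 0.69, "odba_ms2", "mgkg h",
                                 "steady", NULL, "MO2 vs ODBA, swim tunnel"),
      unsteady = calibration_model(59.94, 175.28, 0.71, "odba_ms2", "mgkg h",
                                   "unsteady", NULL,
                                   "MO2 vs ODBA, swim tunnel")
    )
  )
}

#' Free-swimming energetics report
#'
#' Transfers the swim-tunnel calibrations to a free-swimming speed: predicts
#' external acceleration and ODBA at the given speed and chains each into its
#' MO2 calibration.
#'
#' @param speed Swimming speed, m s^-1.
#' @param flow_condition `"steady"` or `"unsteady"`.
#' @param registry Calibration registry (defaults to
#'   [calibration_registry()]).
#' @param observed Optional named list of observed values
#'   (`ext_accel_mg`, `odba_ms2`) to carry into the report; when supplied the
#'   MO2 chains are also evaluated at the observed metrics.
#' @return List of class `energetics_report`.
#' @export
field_energetics_report <- function(speed,
                                    flow_condition = c("steady", "unsteady"),
                                    registry = calibration_registry(),
                                    observed = NULL) {
  flow_condition <- match.arg(flow_condition)
  accel_chain <- chain_predict_mo2(registry$accel_vs_speed[[flow_condition]],
                                   registry$mo2_vs_accel[[flow_condition]],
                                   speed)
  odba_chain <- chain_predict_mo2(registry$odba_vs_speed[[flow_condition]],
                                  registry$mo2_vs_odba[[flow_condition]],
                                  speed)
  rep <- list(flow_condition = flow_condition, speed = speed,
              predicted_ext_accel = accel_chain$activity,
              predicted_odba = odba_chain$activity,
              predicted_mo2_from_accel = accel_chain$mo2,
              predicted_mo2_from_odba = odba_chain$mo2,
              extrapolated = accel_chain$extrapolated | odba_chain$extrapolated)
  if (!is.null(observed)) {
    rep$observed <- observed
    if (!is.null(observed$ext_accel_mg)) {
      rep$mo2_at_observed_accel <- as.numeric(
        predict(registry$mo2_vs_accel[[flow_condition]],
                observed$ext_accel_mg))
    }
    if (!is.null(observed$odba_ms2)) {
      rep$mo2_at_observed_odba <- as.numeric(
        predict(registry$mo2_vs_odba[[flow_condition]], observed$odba_ms2))
    }
  }
  class(rep) <- "energetics_report"
  rep
}

#' @export
print.energetics_report <- function(x, ...) {
  cat(sprintf("Free-swimming energetics at %.2f m/s (%s flow)\n",
              x$speed, x$flow_condition))
  cat(sprintf("  predicted external acceleration: %.2f milli-g\n",
              x$predicted_ext_accel))
  cat(sprintf("  predicted ODBA: %.2f m/s^2\n", x$predicted_odba))
  cat(sprintf("  predicted MO2 (acceleration chain): %.1f mg/kg/h\n",
              x$predicted_mo2_from_accel))
  cat(sprintf("  predicted MO2 (ODBA chain): %.1f mg/kg/h\n",
              x$predicted_mo2_from_odba))
  if (isTRUE(x$extrapolated)) cat("  [extrapolated beyond calibrated range]\n")
  invisible(x)
}
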