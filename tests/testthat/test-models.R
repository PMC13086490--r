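test_that("fit_line recovers exact lines and flags null relationships", {
  m <- fit_line(1:5, 2 * (1:5) + 1)
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$intercept, 1, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)

  set.seed(31)
  null <- fit_line(1:50, rnorm(50))
  expect_lt(null$r_squared, 0.1)

  expect_error(fit_line(rep(1, 5), 1:5), "constant")
  expect_error(fit_line(1:2, 1:2), "3 points")
})

test_that("refitting data generated from a registry line recovers it", {
  reg <- calibration_registry()
  truth <- reg$accel_vs_speed$steady
  u <- seq(0.30, 0.75, by = 0.15)
  # noise-free: coefficients to 6 decimals
  m0 <- fit_line(u, truth$slope * u + truth$intercept)
  expect_equal(m0$slope, truth$slope, tolerance = 1e-6)
  expect_equal(m0$intercept, truth$intercept, tolerance = 1e-6)

  # small perturbations of the per-speed means leave the slope within 5 %
  set.seed(12)
  slopes <- replicate(20, {
    y <- truth$slope * u + truth$intercept + rnorm(length(u), 0, 0.05)
    fit_line(u, y)$slope
  })
  expect_true(all(abs(slopes - truth$slope) / truth$slope < 0.05))
})

test_that("the registry holds the eight published calibrations", {
  reg <- calibration_registry()
  expect_length(unlist(reg, recursive = FALSE), 8)
  expect_equal(coef(reg$odba_vs_speed$unsteady),
               c(intercept = 0.53, slope = 0.24))
  expect_equal(reg$odba_vs_speed$unsteady$r_squared, 0.92)
  expect_equal(reg$odba_vs_speed$unsteady$x_convention, "speed_step_index")
  expect_equal(coef(reg$mo2_vs_odba$steady),
               c(intercept = 151.99, slope = 78.83))
  expect_equal(reg$accel_vs_speed$steady$r_squared, 0.99)
  expect_equal(reg$mo2_vs_accel$steady$r_squared, 0.56)
})

test_that("registry predictions reproduce the published free-swimming values", {
  reg <- calibration_registry()
  expect_equal(round(as.numeric(predict(reg$accel_vs_speed$steady, 0.50)), 2),
               13.04)
  # printed 13.74; coefficient rounding leaves +/- 0.02
  expect_equal(as.numeric(predict(reg$accel_vs_speed$unsteady, 0.50)),
               13.74, tolerance = 0.02 / 13.74)
  expect_equal(round(as.numeric(predict(reg$odba_vs_speed$unsteady, 0.50)), 2),
               1.33)
})

test_that("predict is exactly linear and flags extrapolation", {
  reg <- calibration_registry()
  m <- reg$accel_vs_speed$steady
  x1 <- 0.4; x2 <- 0.6
  expect_equal(as.numeric(predict(m, x1)) + as.numeric(predict(m, x2)) -
                 as.numeric(predict(m, 0)),
               as.numeric(predict(m, x1 + x2)), tolerance = 1e-12)
  expect_false(attr(predict(m, 0.5), "extrapolated"))
  expect_true(attr(predict(m, 0.9), "extrapolated"))
  expect_true(attr(predict(m, 0.1), "extrapolated"))
})

test_that("MO2 chaining composes predictions and enforces units", {
  reg <- calibration_registry()
  # observed steady ODBA 1.13 m/s^2 feeds the ODBA-MO2 line: ~241
  expect_equal(as.numeric(predict(reg$mo2_vs_odba$steady, 1.13)),
               241.07, tolerance = 1e-4)

  chain <- chain_predict_mo2(reg$odba_vs_speed$steady,
                             reg$mo2_vs_odba$steady, 0.5)
  expect_equal(chain$mo2,
               78.83 * as.numeric(predict(reg$odba_vs_speed$steady, 0.5)) +
                 151.99, tolerance = 1e-9)

  # identity second stage returns the first-stage prediction
  ident <- calibration_model(1, 0, 1, "odba_ms2", "mgkg h", "steady")
  expect_equal(chain_predict_mo2(reg$odba_vs_speed$steady, ident, 0.5)$mo2,
               as.numeric(predict(reg$odba_vs_speed$steady, 0.5)))

  # an acceleration output cannot feed an ODBA predictor
  expect_error(chain_predict_mo2(reg$accel_vs_speed$steady,
                                 reg$mo2_vs_odba$steady, 0.5), "mismatch")
})

test_that("full pipeline consistency: regenerated swim-tunnel session
           reproduces registry slopes within 5 %", {
  reg <- calibration_registry()
  speeds <- seq(0.30, 0.75, by = 0.15)
  ext <- sapply(seq_along(speeds), function(i) {
    tri <- gen_triaxial(speeds[i], duration = 60, noise_sd = 0.002,
                        seed = 300 + i)
    sp <- split_static_dynamic(tri$trace$ax_g, tri$trace$ay_g,
                               tri$trace$az_g)
    external_acceleration(sp$dynamic)
  })
  refit <- fit_line(speeds, ext)
  expect_equal(refit$slope, reg$accel_vs_speed$steady$slope,
               tolerance = 0.05)
  expect_gt(refit$r_squared, 0.95)
})

test_that("the energetics report carries both MO2 chains", {
  rep <- field_energetics_report(0.5, "unsteady",
                                 observed = list(odba_ms2 = 1.13))
  expect_equal(round(rep$predicted_ext_accel, 2), 13.75)
  expect_equal(round(rep$predicted_odba, 2), 1.33)
  expect_equal(rep$predicted_mo2_from_odba,
               59.94 * rep$predicted_odba + 175.28, tolerance = 1e-9)
  expect_equal(rep$mo2_at_observed_odba, 59.94 * 1.13 + 175.28,
               tolerance = 1e-9)
})
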