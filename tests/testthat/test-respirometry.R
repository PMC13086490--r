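test_that("compute_mo2 matches hand arithmetic and handles degenerate slopes", {
  cfg <- default_cfg()
  # 5 % decline over 15 min: 0.05 * 8 * 30 / (0.46 * 0.25)
  t <- seq(0, 900, by = 2)
  rec <- compute_mo2(t, 100 - (5 / 900) * t, cfg)
  expect_equal(rec$mo2, 104.35, tolerance = 1e-4)

  # zero decline gives zero rate
  expect_equal(compute_mo2(t, rep(80, length(t)), cfg)$mo2, 0)

  # rising oxygen flags the record and returns zero
  expect_warning(bad <- compute_mo2(t, 80 + 0.01 * t, cfg))
  expect_equal(bad$mo2, 0)
  expect_true(bad$failed)

  expect_error(compute_mo2(t[1:10], rep(90, 10), cfg), "30 samples")
  expect_error(compute_mo2(rev(t), 100 - (5 / 900) * t, cfg), "increasing")
})

test_that("MO2 scales linearly in decline and volume, inversely in mass", {
  cfg <- default_cfg()
  tr <- linear_o2_trace(213, cfg)
  base <- compute_mo2(tr$time_s, tr$do_percent, cfg)$mo2
  expect_equal(base, 213, tolerance = 1e-9)

  # doubled decline (same duration) doubles the rate
  tr2 <- tr; tr2$do_percent <- 100 - 2 * (100 - tr$do_percent)
  expect_equal(compute_mo2(tr2$time_s, tr2$do_percent, cfg)$mo2, 2 * base,
               tolerance = 1e-9)

  # doubled volume doubles, doubled mass halves
  cfg_v <- respiro_config(chamber_volume = 60, body_mass = 0.46)
  expect_equal(compute_mo2(tr$time_s, tr$do_percent, cfg_v)$mo2, 2 * base,
               tolerance = 1e-9)
  cfg_m <- respiro_config(body_mass = 0.92)
  expect_equal(compute_mo2(tr$time_s, tr$do_percent, cfg_m)$mo2, base / 2,
               tolerance = 1e-9)
})

test_that("background subtraction corrects, clamps and flags", {
  rec <- data.frame(speed = 0.3, mo2 = 220, background_corrected = FALSE,
                    replicate = 1L, failed = FALSE)
  out <- subtract_background(rec, 10)
  expect_equal(out$mo2, 210)
  expect_true(out$background_corrected)

  rec$mo2 <- 5
  expect_warning(clamped <- subtract_background(rec, 10), "clamping")
  expect_equal(clamped$mo2, 0)

  rec$mo2 <- 213
  expect_equal(subtract_background(rec, 0)$mo2, 213)
})

test_that("COT follows the unit conversion and composes with MO2", {
  expect_equal(compute_cot(307, 0.9), 307 / 3.24, tolerance = 1e-12)
  expect_equal(compute_cot(123.4, 1 / 3.6), 123.4)  # 1 km/h identity
  expect_equal(compute_cot(0, 0.5), 0)
  expect_error(compute_cot(100, 0), "speed")

  # algebraic identity on random inputs: COT(MO2(trace)) = MO2 / (3.6 U)
  set.seed(42)
  cfg <- default_cfg()
  for (i in 1:5) {
    mo2_true <- runif(1, 100, 400)
    u <- runif(1, 0.2, 1)
    tr <- linear_o2_trace(mo2_true, cfg)
    mo2 <- compute_mo2(tr$time_s, tr$do_percent, cfg)$mo2
    expect_equal(compute_cot(mo2, u), mo2 / (3.6 * u), tolerance = 1e-12)
  }
})

test_that("COT parabola fit finds the analytic vertex", {
  u <- c(0.15, 0.3, 0.45, 0.6, 0.75, 0.9)
  cc <- fit_cot_curve(u, 100 + 50 * (u - 0.5)^2)
  expect_true(cc$valid)
  expect_equal(cc$u_opt, 0.5, tolerance = 1e-9)
  expect_equal(cc$cot_min, 100, tolerance = 1e-9)
})

test_that("U_opt equals the grid-search minimizer of the fitted polynomial", {
  # COT derived from MO2 = a + b U^3 is not a parabola; the contract is that
  # the vertex matches an independent grid minimizer of the *fitted* curve
  u <- seq(0.15, 0.9, by = 0.15)
  mo2 <- 180 + 160 * u^3
  cc <- fit_cot_curve(u, compute_cot(mo2, u))
  expect_true(cc$valid)
  grid <- seq(min(u), max(u), by = 1e-4)
  u_grid <- grid[which.min(predict(cc, grid))]
  expect_equal(cc$u_opt, u_grid, tolerance = 1e-4)
  expect_true(cc$u_opt >= min(u) && cc$u_opt <= max(u))
})

test_that("degenerate COT inputs are rejected or flagged", {
  u <- seq(0.15, 0.9, by = 0.15)
  # monotone decreasing, concave fit: no interior minimum
  cc <- fit_cot_curve(u, 500 - 400 * u + 100 * u^2 - 300 * u^2)
  expect_false(cc$valid)
  expect_error(fit_cot_curve(u[1:3], (1:3)), "4 points")
  expect_error(fit_cot_curve(rep(0.5, 5), 1:5), "distinct")
})

test_that("U_crit boundary identities and monotonicity hold", {
  expect_equal(compute_ucrit(0.75, 0.15, 15, 30), 0.825)
  expect_equal(compute_ucrit(0.75, 0.15, 0, 30), 0.75)
  expect_equal(compute_ucrit(0.75, 0.15, 30, 30), 0.90)
  expect_error(compute_ucrit(0.75, 0.15, 31, 30), "fatigue")
  # monotone increasing in time-to-fatigue
  vals <- sapply(seq(0, 30, by = 5),
                 function(ti) compute_ucrit(0.75, 0.15, ti, 30))
  expect_true(all(diff(vals) > 0))
})

test_that("solid-blocking check is strict at 10 %", {
  expect_true(check_solid_blocking(50, 625))     # 25 x 25 cm section
  expect_false(check_solid_blocking(62.5, 625))  # exactly 10 %
  expect_true(check_solid_blocking(6.25, 625))
  expect_error(check_solid_blocking(700, 625), "impossible")
})

test_that("Fulton's K follows the cubic-length convention", {
  expect_equal(fulton_k(460, 30), 100 * 460 / 27000)
  expect_equal(fulton_k(1000, 10), 100)
  expect_equal(fulton_k(460, 60), fulton_k(460, 30) / 8)
  expect_error(fulton_k(-1, 30))
})

test_that("replicate recovery: 0.5 % sensor noise keeps means within 5 %", {
  cfg <- default_cfg()
  sess <- gen_respiro_session(cfg, noise_sd = 0.5, seed = 99)
  res <- analyse_respiro_session(sess$trace, cfg)
  truth <- unique(sess$truth[, c("speed", "mo2_true")])
  merged <- merge(res$summary, truth, by.x = "speed_mps", by.y = "speed")
  expect_equal(nrow(merged), 5)
  expect_true(all(abs(merged$mo2 - merged$mo2_true) / merged$mo2_true < 0.05))
})
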