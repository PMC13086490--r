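test_that("day/night labelling partitions all 24 hours exhaustively", {
  labels <- label_period(0:23)
  expect_equal(sum(labels == "day"), 12)
  expect_equal(sum(labels == "night"), 12)
  expect_equal(label_period(9), "day")    # morning feeding hour
  expect_equal(label_period(3), "night")
  # boundary instants under the inclusive-hour convention
  t1 <- as.POSIXct("2024-03-04 17:59:00", tz = "UTC")
  t2 <- as.POSIXct("2024-03-04 18:00:00", tz = "UTC")
  expect_equal(label_period(t1), "day")
  expect_equal(label_period(t2), "night")
  expect_equal(label_period(as.POSIXct("2024-03-04 05:59:00", tz = "UTC")),
               "night")
})

test_that("hourly aggregation averages per fish and reports group s.e.m.", {
  flat <- flat_sentinel(n_fish = 1, hr = 70)
  agg <- hourly_aggregate(flat)
  expect_true(all(agg$group$hr_bpm == 70))

  two <- rbind(
    transform(flat_sentinel(n_fish = 1, hr = 60), fish_id = "a"),
    transform(flat_sentinel(n_fish = 1, hr = 80), fish_id = "b"))
  agg2 <- hourly_aggregate(two)
  expect_true(all(agg2$group$hr_bpm == 70))
  expect_true(all(abs(agg2$group$hr_bpm_sem - 10) < 1e-12))

  # invariant to record order and to duplicating identical records
  shuffled <- two[sample(nrow(two)), ]
  expect_equal(hourly_aggregate(shuffled)$group, agg2$group)
  duplicated <- rbind(two, two)
  expect_equal(hourly_aggregate(duplicated)$group, agg2$group)
})

test_that("the synthetic M-shaped day profile peaks near feeding hours", {
  sen <- gen_sentinel(n_fish = 4, days_per_phase = 4, seed = 6)
  agg <- hourly_aggregate(sen$data)
  g <- agg$group[agg$group$treatment == "steady", ]
  g <- g[order(g$hour), ]
  day_hr <- g$hr_bpm[g$hour %in% 6:17]
  night_hr <- g$hr_bpm[g$hour %in% c(18:23, 0:5)]
  expect_gt(mean(day_hr), mean(night_hr))
  peaks <- g$hour[g$hour %in% 6:17][order(day_hr, decreasing = TRUE)][1:2]
  expect_true(all(peaks %in% c(8, 9, 10, 15, 16, 17)))
})

test_that("day/night summary recovers configured cells and orderings", {
  flat <- flat_sentinel(n_fish = 3, hr = 70)
  dn <- day_night_summary(flat)
  expect_true(all(dn$hr_bpm == 70))  # constant input: identical cells

  sen <- gen_sentinel(seed = 13)
  dn <- day_night_summary(sen$data)
  cells <- sentinel_defaults()
  get <- function(tr, pe, col = "hr_bpm") {
    dn[dn$treatment == tr & dn$period == pe, col]
  }
  expect_equal(get("unsteady", "day"), 73.20, tolerance = 1 / 73.20)
  expect_equal(get("steady", "day"), 71.10, tolerance = 1 / 71.10)
  # VAR ordering: unsteady exceeds steady in both periods
  expect_gt(get("unsteady", "day", "var_mg2"),
            get("steady", "day", "var_mg2"))
  expect_gt(get("unsteady", "night", "var_mg2"),
            get("steady", "night", "var_mg2"))
})

test_that("a noise-free generator reproduces the cells exactly", {
  params <- sentinel_defaults()
  for (m in names(params)) {
    params[[m]]$residual_sd <- 0
    params[[m]]$intercept_sd <- 0
    params[[m]]$feeding_amp <- 0
  }
  sen <- gen_sentinel(n_fish = 2, days_per_phase = 2, params = params,
                      seed = 1)
  dn <- day_night_summary(sen$data)
  for (m in names(params)) {
    for (tr in c("steady", "unsteady")) {
      for (pe in c("day", "night")) {
        expect_equal(dn[dn$treatment == tr & dn$period == pe, m],
                     unname(params[[m]]$cells[paste(tr, pe, sep = ".")]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the mixed model recovers generator fixed effects", {
  sen <- gen_sentinel(n_fish = 6, days_per_phase = 5, seed = 17)
  fit <- fit_activity_lmm(sen$data, "hr_bpm")
  pe <- fixed_effect(fit, "periodday")
  te <- fixed_effect(fit, "treatmentunsteady")
  cells <- sentinel_defaults()$hr_bpm$cells
  true_period <- mean(c(cells["steady.day"] - cells["steady.night"],
                        cells["unsteady.day"] - cells["unsteady.night"]))
  true_treat <- mean(c(cells["unsteady.day"] - cells["steady.day"],
                       cells["unsteady.night"] - cells["steady.night"]))
  expect_lt(abs(pe["estimate"] - true_period), 3 * pe["se"])
  expect_lt(abs(te["estimate"] - true_treat), 3 * te["se"])
  expect_true(is.finite(fit$random_intercept_sd))
  expect_true(fit$residual_sd > 0)
})

test_that("the mixed model enforces its design contract", {
  sen <- gen_sentinel(n_fish = 3, days_per_phase = 2, seed = 23)
  single <- sen$data[sen$data$fish_id == "fish01", ]
  expect_error(fit_activity_lmm(single, "hr_bpm"), "single fish")
  steady_only <- sen$data[sen$data$treatment == "steady", ]
  expect_error(fit_activity_lmm(steady_only, "hr_bpm"), "treatments")
})

test_that("fixed effects are stable under balanced epoch subsampling", {
  sen <- gen_sentinel(n_fish = 6, days_per_phase = 6, seed = 29)
  full <- fixed_effect(fit_activity_lmm(sen$data, "hr_bpm"), "periodday")
  # keep every other epoch (balanced across fish and phases)
  keep <- sen$data[seq(1, nrow(sen$data), by = 2), ]
  half <- fixed_effect(fit_activity_lmm(keep, "hr_bpm"), "periodday")
  expect_lt(abs(full["estimate"] - half["estimate"]),
            3 * sqrt(full["se"]^2 + half["se"]^2))
})
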