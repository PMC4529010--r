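test_that("blended rate mixes emission rates by time share", {
  expect_equal(blended_rate(40, 1, 0.5), 20.5)
  expect_equal(blended_rate(7, 7, 0.3), 7)
  expect_equal(blended_rate(40, 1, 1), 1)
  expect_error(blended_rate(40, 1, 1.2), class = "stoveuse_error_scenario")
})

test_that("exclusive TSF use yields the published baseline concentration", {
  res <- evaluate_scenario(displacement_scenario("tsf", "tier4", 0))
  pm <- res$summary[res$summary$pollutant == "pm25", ]
  expect_equal(pm$kitchen_mean, 40 * 180 / 10800 * 1000, tolerance = 0.005)
  expect_equal(pm$baseline_share, 1)
  expect_equal(pm$new_share, 0)
  expect_false(any(res$targets$meets[res$targets$pollutant == "pm25"]))
})

test_that("source shares at half displacement match the published apportionment", {
  share <- function(new, pollutant) {
    res <- evaluate_scenario(displacement_scenario("tsf", new, 0.5),
                             pollutants = pollutant)
    round(100 * res$summary$baseline_share)
  }
  expect_equal(share("tier4", "pm25"), 98)
  expect_equal(share("tier3", "pm25"), 89)
  expect_equal(share("tier4", "co"), 82)
  expect_equal(share("tier3", "co"), 68)
})

test_that("source shares obey the closed-form identity", {
  reg <- stove_registry()
  set.seed(3)
  for (i in 1:10) {
    d <- runif(1)
    res <- evaluate_scenario(displacement_scenario("tsf", "tier2", d),
                             pollutants = "pm25")
    g_base <- 40 * (1 - d)
    g_new <- 12.5 * d
    expect_equal(res$summary$baseline_share, g_base / (g_base + g_new),
                 tolerance = 1e-9)
  }
})

test_that("block-wise event reallocation agrees with proportional splitting", {
  s <- displacement_scenario("tsf", "tier4", 0.5)
  prop <- evaluate_scenario(s, split = "proportional")$summary
  blocks <- evaluate_scenario(s, split = "blocks")$summary
  expect_equal(blocks$kitchen_mean, prop$kitchen_mean, tolerance = 1e-9)
})

test_that("usage-time inversion matches the closed form and the published limits", {
  cases <- list(
    list(stove = "tsf", target = "pm25_interim1", t = 0.035 * 10800 / 40),
    list(stove = "charcoal_traditional", target = "pm25_interim1",
         t = 0.035 * 10800 / 15),
    list(stove = "tsf", target = "co_24hr", t = 7 * 10800 / 970),
    list(stove = "charcoal_traditional", target = "co_24hr",
         t = 7 * 10800 / 1300)
  )
  for (cs in cases) {
    bis <- max_usage_minutes(cs$stove, target = cs$target)
    cf <- max_usage_minutes(cs$stove, target = cs$target,
                            method = "closed_form")
    expect_equal(bis, cs$t, tolerance = 1e-3)
    expect_equal(cf, cs$t, tolerance = 1e-12)
  }
  # the printed guidance: ~10 min/day TSF and ~25 min/day charcoal for PM2.5,
  # TSF CO quoted as a conservative 75
  expect_equal(guidance_round(max_usage_minutes("tsf", target = "pm25_interim1"),
                           "minutes"), 10)
  expect_equal(guidance_round(max_usage_minutes("charcoal_traditional",
                                             target = "pm25_interim1"),
                           "minutes"), 25)
  expect_equal(guidance_round(max_usage_minutes("tsf", target = "co_24hr"),
                           "minutes", mode = "down"), 75)
  # even 5 min/day of TSF use exceeds the final PM2.5 guideline
  expect_lt(max_usage_minutes("tsf", target = "pm25_final"), 5)
})

test_that("tier-stove usage limits: the printed 15/30/75/375 sequence follows the PM2.5 target, not CO", {
  tiers <- c("tier1", "tier2", "tier3", "tier4")
  via_pm <- vapply(tiers, function(s) {
    max_usage_minutes(s, target = "pm25_interim1", method = "closed_form")
  }, numeric(1))
  via_co <- vapply(tiers, function(s) {
    max_usage_minutes(s, target = "co_24hr", method = "closed_form")
  }, numeric(1))
  expect_equal(unname(via_pm), 0.035 * 10800 / c(28.5, 12.5, 5, 1),
               tolerance = 1e-12)
  # PM interpretation lands within 5 min of the printed sequence
  expect_true(all(abs(via_pm - c(15, 30, 75, 375)) <= 5))
  # the CO rates give a different sequence (~95/136/166/360)
  expect_equal(unname(via_co), 7 * 10800 / c(795, 555, 455, 210),
               tolerance = 1e-12)
  expect_gt(max(abs(via_co - c(15, 30, 75, 375))), 30)
})

test_that("usage limit saturates at continuous use for very clean stoves", {
  clean <- tibble::tibble(stove = "ultra", pm_rate = 0.1, co_rate = 1,
                          thermal_efficiency = 0.5)
  expect_identical(max_usage_minutes(clean, target = "co_24hr"), 1440)
  zero <- tibble::tibble(stove = "none", pm_rate = 0, co_rate = 0,
                         thermal_efficiency = 0.5)
  expect_error(max_usage_minutes(zero, target = "pm25_interim1"),
               class = "stoveuse_error_scenario")
})

test_that("displacement inversion reproduces the published thresholds", {
  expect_equal(round(100 * required_displacement("tsf", "tier4",
                                                 goal_kitchen = 166)), 77)
  expect_equal(round(100 * required_displacement("tsf", "tier3",
                                                 goal_kitchen = 166)), 86)
  expect_equal(round(100 * required_displacement("tsf", "tier4",
                                                 goal_exposure = 35)), 94)
  # 50% exposure reduction with tiers 2/3/4: ~73%, 57%, 51%
  d50 <- vapply(c("tier2", "tier3", "tier4"), function(s) {
    required_displacement("tsf", s, goal_reduction = 0.5)
  }, numeric(1))
  expect_equal(round(100 * unname(d50)), c(73, 57, 51))
  # 75% exposure reduction with tiers 3/4: 86% and 77%
  d75 <- vapply(c("tier3", "tier4"), function(s) {
    required_displacement("tsf", s, goal_reduction = 0.75)
  }, numeric(1))
  expect_equal(round(100 * unname(d75)), c(86, 77))
  expect_identical(required_displacement("tsf", "tier4",
                                         goal_kitchen = 40 * 180 / 10800 * 1000),
                   0)
})

test_that("unreachable goals are signalled", {
  expect_error(required_displacement("tsf", "tier1", goal_kitchen = 35),
               class = "stoveuse_error_unreachable")
  expect_error(required_displacement("tier4", "tsf", goal_kitchen = 100),
               class = "stoveuse_error_scenario")
})

test_that("closed-form and bisection inversions agree and bracket the goal", {
  goals <- list(list(goal_kitchen = 166), list(goal_kitchen = 333),
                list(goal_reduction = 0.5), list(goal_exposure = 100))
  for (g in goals) {
    d_cf <- do.call(required_displacement, c(list("tsf", "tier3"), g))
    d_bi <- do.call(required_displacement,
                    c(list("tsf", "tier3"), g, method = "bisection"))
    expect_equal(d_bi, d_cf, tolerance = 1e-4)
    # inversion consistency: the goal is met at d and violated at d - 0.005
    mean_at <- function(d) {
      evaluate_scenario(displacement_scenario("tsf", "tier3", d),
                        pollutants = "pm25")$summary$kitchen_mean
    }
    goal_ug <- if (!is.null(g$goal_kitchen)) g$goal_kitchen
    else if (!is.null(g$goal_exposure)) g$goal_exposure / 0.628
    else (1 - g$goal_reduction) * mean_at(0)
    expect_lte(mean_at(d_cf), goal_ug * (1 + 1e-6))
    if (d_cf > 0.005) expect_gt(mean_at(d_cf - 0.005), goal_ug)
  }
})

test_that("displacement sweeps are affine with the published endpoints", {
  sweep <- displacement_sweep(grid = c(0, 0.25, 0.5, 0.75, 1))
  pm4 <- sweep[sweep$new_stove == "tier4" & sweep$pollutant == "pm25", ]
  expect_equal(pm4$kitchen_mean[pm4$displacement == 0], 666.7,
               tolerance = 0.005)
  expect_equal(pm4$kitchen_mean[pm4$displacement == 1], 16.67,
               tolerance = 0.005)
  # interpolation: midpoint equals the mean of the endpoints
  expect_equal(pm4$kitchen_mean[pm4$displacement == 0.5],
               (pm4$kitchen_mean[pm4$displacement == 0] +
                  pm4$kitchen_mean[pm4$displacement == 1]) / 2,
               tolerance = 0.005)
  # the d = 0 row is the baseline, identical across new stoves
  d0 <- sweep[sweep$displacement == 0 & sweep$pollutant == "pm25", ]
  expect_equal(diff(range(d0$kitchen_mean)), 0, tolerance = 1e-9)
})

test_that("affinity holds exactly on the closed form and within 0.5% on simulation", {
  grid <- seq(0, 1, by = 0.1)
  # closed form: interpolation residual below 1e-9 relative
  cf <- closed_form_daily_mean(blended_rate(40, 5, grid), 180, ref_kitchen())
  interp <- cf[1] + grid * (cf[length(cf)] - cf[1])
  expect_lt(max(abs(cf - interp)) / max(cf), 1e-9)
  # simulation route
  sweep <- displacement_sweep(new_stoves = "tier3", grid = grid,
                              pollutants = "pm25")
  sim <- sweep$kitchen_mean
  interp_sim <- sim[1] + grid * (sim[length(sim)] - sim[1])
  expect_lt(max(abs(sim - interp_sim)) / max(sim), 0.005)
})

test_that("charcoal-baseline sweeps satisfy the same structure", {
  sweep <- displacement_sweep(baseline = "charcoal_traditional",
                              new_stoves = "tier4", grid = c(0, 0.5, 1),
                              pollutants = "pm25")
  expect_equal(sweep$kitchen_mean[sweep$displacement == 0],
               15 * 180 / 10800 * 1000, tolerance = 0.005)
  expect_equal(sweep$kitchen_mean[sweep$displacement == 0.5],
               mean(sweep$kitchen_mean[sweep$displacement %in% c(0, 1)]),
               tolerance = 0.005)
  d <- 0.5
  expect_equal(sweep$baseline_share[sweep$displacement == d],
               (1 - d) * 15 / ((1 - d) * 15 + d * 1), tolerance = 1e-9)
})

test_that("tier band sweeps bracket the representative curve", {
  grid <- seq(0, 1, by = 0.25)
  tb <- tier_band_sweep("pm_indoor_emissions", grid = grid)
  t3 <- tb[tb$tier == 3 & tb$displacement == 1, ]
  expect_equal(t3$kitchen_mean[t3$bound == "lower"], 2 * 180 / 10800 * 1000,
               tolerance = 1e-9)
  expect_equal(t3$kitchen_mean[t3$bound == "upper"], 8 * 180 / 10800 * 1000,
               tolerance = 1e-9)
  wide <- tidyr::pivot_wider(tb, id_cols = c("tier", "displacement"),
                             names_from = "bound",
                             values_from = "kitchen_mean")
  expect_true(all(wide$lower <= wide$representative + 1e-12 &
                    wide$representative <= wide$upper + 1e-12))
  # the tier-0 lower bound (40 mg/min) reproduces the TSF curve
  tb0 <- tier_band_sweep("pm_indoor_emissions", grid = grid, tiers = 0)
  t0 <- tb0[tb0$bound == "lower", ]
  expect_equal(t0$kitchen_mean,
               closed_form_daily_mean(blended_rate(40, 40, grid), 180,
                                      ref_kitchen()) * 1000,
               tolerance = 1e-12)
})

test_that("scenario results expose tidy and glance methods", {
  res <- evaluate_scenario(displacement_scenario("tsf", "tier4", 0.5))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$pollutant, c("pm25", "co"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$displacement, 0.5)
  expect_false(gl$all_targets_met)
})
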