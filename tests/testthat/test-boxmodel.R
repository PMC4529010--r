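test_that("the one-step update matches its analytic limits", {
  k <- ref_kitchen()
  expect_identical(step_concentration(0, 0, k, 17), 0)
  # steady state G/(alpha*V) = 40 / (0.25 * 30)
  expect_equal(step_concentration(0, 40, k, 1e7), 40 / (0.25 * 30),
               tolerance = 1e-12)
  # pure exponential decay over one minute
  c0 <- 2.5
  expect_equal(step_concentration(c0, 0, k, 1), c0 * exp(-0.25),
               tolerance = 1e-12)
  expect_error(step_concentration(-1, 0, k), class = "stoveuse_error_boxmodel")
  expect_error(step_concentration(0, -1, k), class = "stoveuse_error_boxmodel")
  expect_error(step_concentration(0, 1, k, dt = 0),
               class = "stoveuse_error_boxmodel")
})

test_that("the vectorised simulation reproduces a naive minute loop exactly", {
  k <- kitchen(22, 31)
  sched <- cooking_schedule(c(100, 500, 900), c(45, 80, 30), c(12, 30, 5))
  series <- simulate_day(sched, k, c_initial = 0.4)
  tot <- series_total(series)
  oracle <- naive_trace(schedule_rates(sched), k$alpha, k$volume, c0 = 0.4)
  expect_equal(tot$concentration, oracle, tolerance = 1e-12)
})

test_that("daily means match the mass-balance oracle within 0.5%", {
  k <- ref_kitchen()
  one_block <- simulate_day(cooking_schedule(420, 180, 40), k)
  expect_equal(daily_mean(one_block), 7200 / 10800, tolerance = 0.005)
  three <- simulate_day(cooking_schedule(c(420, 720, 1080), 60, 40), k)
  expect_equal(daily_mean(three), daily_mean(one_block), tolerance = 0.005)
  expect_equal(closed_form_daily_mean(40, 180, k), 7200 / 10800,
               tolerance = 1e-12)
  expect_identical(closed_form_daily_mean(40, 0, k), 0)
})

test_that("empty and degenerate schedules behave", {
  k <- ref_kitchen()
  empty <- cooking_schedule(numeric(0), numeric(0), numeric(0))
  series <- simulate_day(empty, k)
  expect_true(all(series$concentration == 0))
  expect_identical(daily_mean(series), 0)
  const <- tibble::tibble(minute = 1:10, concentration = 3.2)
  expect_equal(daily_mean(const), 3.2)
})

test_that("schedule validation enforces the single-cook assumption", {
  expect_error(cooking_schedule(c(0, 30), c(60, 10), 5),
               class = "stoveuse_error_schedule")
  expect_error(cooking_schedule(1400, 60, 5),
               class = "stoveuse_error_schedule")
  expect_error(cooking_schedule(10, 10, -1),
               class = "stoveuse_error_schedule")
  expect_error(cooking_schedule(10.5, 10, 1),
               class = "stoveuse_error_schedule")
})

test_that("mass balance holds to numerical tolerance for decayed schedules", {
  k <- kitchen(25, 20)
  sched <- cooking_schedule(c(60, 400, 800), c(90, 120, 60), c(8, 22, 40))
  tot <- series_total(simulate_day(sched, k))
  emitted <- sum(sched$rate * sched$duration)
  recovered <- k$alpha * k$volume * sum(tot$concentration) +
    k$volume * tot$concentration[1440]
  expect_equal(recovered, emitted, tolerance = 1e-8)
})

test_that("a schedule running to midnight still balances within 0.5%", {
  k <- ref_kitchen()
  sched <- cooking_schedule(1260, 180, 40)
  tot <- series_total(simulate_day(sched, k))
  emitted <- 40 * 180
  recovered <- k$alpha * k$volume * sum(tot$concentration) +
    k$volume * tot$concentration[1440]
  expect_equal(recovered, emitted, tolerance = 0.005)
})

test_that("the model is linear and per-source traces superpose", {
  k <- ref_kitchen()
  sched <- cooking_schedule(c(420, 720), c(60, 90), c(40, 12),
                            source = c("a", "b"))
  series <- simulate_day(sched, k)
  # superposition: component sum equals a joint single-source simulation
  joint <- cooking_schedule(c(420, 720), c(60, 90), c(40, 12))
  expect_equal(series_total(series)$concentration,
               series_total(simulate_day(joint, k))$concentration,
               tolerance = 1e-12)
  # linearity: doubling rates doubles concentrations
  doubled <- cooking_schedule(c(420, 720), c(60, 90), 2 * c(40, 12),
                              source = c("a", "b"))
  expect_equal(series_total(simulate_day(doubled, k))$concentration,
               2 * series_total(series)$concentration, tolerance = 1e-12)
})

test_that("a held source approaches steady state within 0.01% after an hour", {
  k <- ref_kitchen()
  series <- simulate_day(cooking_schedule(0, 120, 40), k)
  tot <- series_total(series)
  expect_equal(tot$concentration[60], 40 / (0.25 * 30), tolerance = 1e-4)
})

test_that("daily mean is nondecreasing in rate and duration", {
  k <- ref_kitchen()
  means_rate <- vapply(c(5, 10, 20, 40), function(g) {
    daily_mean(simulate_day(cooking_schedule(420, 60, g), k))
  }, numeric(1))
  expect_true(all(diff(means_rate) > 0))
  means_dur <- vapply(c(30, 60, 120, 240), function(dur) {
    daily_mean(simulate_day(cooking_schedule(420, dur, 40), k))
  }, numeric(1))
  expect_true(all(diff(means_dur) > 0))
})

test_that("event placement shifts the daily mean by less than 0.5%", {
  k <- ref_kitchen()
  placements <- list(
    cooking_schedule(c(0, 300, 600), 60, 40),
    cooking_schedule(c(420, 720, 1080), 60, 40),
    cooking_schedule(60, 180, 40),
    cooking_schedule(c(100, 200, 300, 400, 500, 600), 30, 40)
  )
  means <- vapply(placements, function(s) daily_mean(simulate_day(s, k)),
                  numeric(1))
  expect_lt(diff(range(means)) / mean(means), 0.005)
})

test_that("closed form tracks the simulation for schedules ending an hour before midnight", {
  k <- kitchen(35, 18)
  set.seed(7)
  for (i in 1:20) {
    dur <- sample(20:120, 1)
    start <- sample(0:(1380 - dur), 1)
    g <- runif(1, 1, 50)
    sim <- daily_mean(simulate_day(cooking_schedule(start, dur, g), k))
    expect_equal(sim, closed_form_daily_mean(g, dur, k), tolerance = 0.005)
  }
})

test_that("overnight carryover is negligible at the default ventilation", {
  k <- ref_kitchen()
  sched <- cooking_schedule(c(420, 720, 1080), 60, 40)
  days <- spinup_carryover(sched, k, days = 3)
  expect_lt(abs(days$daily_mean[3] - days$daily_mean[1]) / days$daily_mean[1],
            0.001)
})

test_that("initial concentration and background appear as their own components", {
  k <- ref_kitchen()
  series <- simulate_day(cooking_schedule(420, 60, 40), k,
                         c_initial = 1, background = 0.01)
  expect_setequal(unique(series$source), c("stove", "initial", "background"))
  init <- series[series$source == "initial", ]
  expect_equal(init$concentration, exp(-0.25 * (1:1440)), tolerance = 1e-12)
})
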