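# Closed-form clearance time, deaths and trajectory. Frozen expected
# values were computed with an independent step-by-step Euler integration
# (agreeing to <1e-5 relative at step 0.001 day).

test_that("clearance time matches frozen oracle values and edge cases", {
  p <- default_params()
  # doubled capacity: 130.952 days (Euler oracle: 130.95241)
  expect_equal(clearance_time(4989, 0.36, 13027) * 365, 130.95247,
               tolerance = 1e-6)
  # +20% capacity: 531.63 days
  expect_equal(clearance_time(4989, 0.36, 2605.4) * 365, 531.62812,
               tolerance = 1e-6)
  # empty backlog clears immediately
  expect_equal(clearance_time(0, 0.36, 100), 0)
  # mu -> 0 limit: tc = W0/Te
  expect_equal(clearance_time(100, 1e-12, 365) * 365, 100)
  # vectorised over Te
  expect_equal(clearance_time(4989, 0.36, c(13027, 2605.4)) * 365,
               c(130.95247, 531.62812), tolerance = 1e-6)
})

test_that("clearance time rejects non-clearing regimes", {
  expect_error(clearance_time(4989, 0.36, 0), "cannot clear")
  expect_error(clearance_time(4989, 0.36, -10), "cannot clear")
  expect_error(clearance_time(4989, -0.5, 100), "non-clearing regime")
  expect_error(clearance_time(-1, 0.36, 100), "nonnegative")
})

test_that("deaths at clearance follow the W0 - Te*tc balance", {
  tc <- clearance_time(4989, 0.36, 13027)
  expect_equal(deaths_at_clearance(4989, 13027, tc), 315.2525,
               tolerance = 1e-6)
  tc20 <- clearance_time(4989, 0.36, 3915)
  expect_equal(deaths_at_clearance(4989, 3915, tc20), 882.754,
               tolerance = 1e-5)
  # zero mortality: everyone is treated, nobody dies
  expect_equal(deaths_at_clearance(100, 365, clearance_time(100, 1e-12, 365)),
               0, tolerance = 1e-6)
  # inconsistent tc (not from the same parameters) is an error, not a clamp
  expect_error(deaths_at_clearance(4989, 13027, 1.0), "inconsistent")
})

test_that("zero-surplus mortality accumulates as W0*(1 - exp(-mu t))", {
  expect_equal(deaths_by_time(4989, 0.36, 1), 1508.2928, tolerance = 1e-6)
  expect_equal(deaths_by_time(4989, 0.36, 0), 0)
  expect_equal(deaths_by_time(4989, 0.36, 1e6), 4989)
  expect_error(deaths_by_time(4989, 0.36, -1), "nonnegative")
  # monotone in t and in mu
  t <- seq(0, 5, by = 0.25)
  expect_true(all(diff(deaths_by_time(4989, 0.36, t)) > 0))
  mus <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(deaths_by_time(4989, mus, 1)) > 0))
})

test_that("trajectory conserves patients and matches the closed forms", {
  p <- default_params()
  # zero surplus: pure exponential decay
  tr0 <- waitlist_trajectory(4989, 0.36, 0, c(0, 0.5, 1))
  expect_equal(tr0$waiting[3], 3480.7072, tolerance = 1e-6)
  expect_equal(tr0$cum_deaths[3], 1508.2928, tolerance = 1e-6)
  expect_equal(tr0$cum_treated, c(0, 0, 0))
  # initial condition
  expect_equal(tr0$waiting[1], 4989)
  expect_equal(tr0$cum_deaths[1], 0)
  # at t = tc the list is empty and deaths equal the closed form
  Te <- 2605.4
  tc <- clearance_time(4989, 0.36, Te)
  tr <- waitlist_trajectory(4989, 0.36, Te, c(0, tc / 2, tc, tc + 0.5))
  expect_equal(tr$waiting[3], 0, tolerance = 1e-6)
  expect_equal(tr$cum_deaths[3], deaths_at_clearance(4989, Te, tc),
               tolerance = 1e-9)
  # conservation at every time up to clearance
  expect_equal(tr$waiting + tr$cum_deaths + tr$cum_treated,
               rep(4989, 4), tolerance = 1e-9)
  # after clearance nothing changes
  expect_equal(tr$cum_treated[4], tr$cum_treated[3])
  expect_error(waitlist_trajectory(4989, 0.36, 100, c(-1, 0)), "nonnegative")
})

test_that("conservation Te*tc + m(tc) = W0 holds across the parameter grid", {
  grid <- expand.grid(W0 = c(500, 2000, 4989, 8000),
                      mu = c(0.05, 0.2, 0.36, 0.6, 0.9),
                      Te = c(300, 1200, 2605.4, 6500, 13027))
  tc <- clearance_time(grid$W0, grid$mu, grid$Te)
  m <- deaths_at_clearance(grid$W0, grid$Te, tc)
  expect_equal(grid$Te * tc + m, grid$W0, tolerance = 1e-9)
})

test_that("outcomes fall monotonically in surplus and respond to hazard", {
  Te <- seq(500, 13027, length.out = 40)
  tc <- clearance_time(4989, 0.36, Te)
  m <- deaths_at_clearance(4989, Te, tc)
  expect_true(all(diff(tc) < 0))
  expect_true(all(diff(m) < 0))
  # higher hazard: more deaths, but the list also empties sooner
  mus <- seq(0.1, 0.8, by = 0.05)
  tc_mu <- clearance_time(4989, mus, 2605.4)
  m_mu <- deaths_at_clearance(4989, 2605.4, tc_mu)
  expect_true(all(diff(m_mu) > 0))
  expect_true(all(diff(tc_mu) < 0))
})

test_that("deaths averted show diminishing returns in extra capacity", {
  Te <- seq(651.35, 13027, length.out = 60)
  m <- deaths_at_clearance(4989, Te, clearance_time(4989, 0.36, Te))
  # convex in Te: each extra unit of capacity saves fewer lives
  expect_true(all(diff(diff(m)) > 0))
})

test_that("small-hazard branch agrees with the W0/Te limit and is continuous", {
  W0 <- 4989; Te <- 2605.4
  expect_lt(abs(clearance_time(W0, 1e-10, Te) - W0 / Te) / (W0 / Te), 1e-6)
  # continuity across the series-branch threshold
  below <- clearance_time(W0, 1e-9, Te)
  above <- clearance_time(W0, 1e-7, Te)
  expect_equal(below, above, tolerance = 1e-4)
})

test_that("clearance_point bundles surplus, time, deaths and treated", {
  p <- default_params()
  res <- clearance_point(p, strategy(capacity_increase = 0.2))
  expect_s3_class(res, "clearance_result")
  expect_equal(res$Te_per_year, 2605.4)
  expect_equal(res$tc_days, 531.62812, tolerance = 1e-6)
  expect_equal(res$deaths + res$treated, p$W0_mean, tolerance = 1e-9)
  expect_error(clearance_point(p, strategy()), "no surplus")
})

test_that("population parameter invariants are enforced", {
  expect_error(population_params(W0_ci = c(5000, 5959)), "lower < mean")
  expect_error(population_params(mu_ci = c(0.5, 0.4)), "lower < mean")
  expect_error(population_params(mu_mean = 1.2, mu_ci = c(0.5, 1.5)),
               "mu_mean")
  expect_error(population_params(rS0 = -5), "positive")
  expect_error(population_params(days_per_year = 360), "365")
})
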