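# Strategy grids, isoclines, and inverse capacity planning.

test_that("point-mode grids are monotone with a non-clearing origin", {
  p <- default_params()
  g <- compute_grid(p, p_axis = seq(0, 0.5, by = 0.125),
                    c_axis = seq(0, 0.5, by = 0.125), mode = "point")
  expect_s3_class(g, "strategy_grid")
  # (p=0, c=0): sentinel, not an exception
  expect_identical(g$tc_days[1, 1], Inf)
  expect_equal(g$deaths[1, 1], deaths_by_time(p$W0_mean, p$mu_mean, 1))
  # outcomes non-increasing along both axes; the deaths comparison only
  # applies across clearing cells (the sentinel is a 1-year death count,
  # not a clearance total, so it is not comparable with its neighbours)
  clearing <- is.finite(g$tc_days)
  for (i in seq_along(g$c_axis)) {
    expect_true(all(diff(g$tc_days[i, ]) <= 0))
    expect_true(all(diff(g$deaths[i, clearing[i, ]]) <= 0))
  }
  for (j in seq_along(g$p_axis)) {
    expect_true(all(diff(g$tc_days[, j]) <= 0))
    expect_true(all(diff(g$deaths[clearing[, j], j]) <= 0))
  }
  # long-format export carries every cell
  df <- as.data.frame(g)
  expect_equal(nrow(df), length(g$p_axis) * length(g$c_axis))
  expect_equal(df$tc_days[df$p == 0.5 & df$c == 0.25],
               g$tc_days["0.250", "0.500"])
})

test_that("the mc-mean grid reproduces the combined-strategy cell", {
  p <- default_params()
  g <- compute_grid(p, p_axis = c(0.2, 0.4), c_axis = c(0.1, 0.2),
                    mode = "mc-mean", n = 10000, seed = 20220616)
  tc <- g$tc_days[2, 2]
  deaths <- g$deaths[2, 2]
  expect_lt(abs(tc - 343), mc_tol(343))
  expect_lt(abs(deaths - 784), mc_tol(784))
})

test_that("inverse planners round-trip against the forward model", {
  p <- default_params()
  set.seed(99)
  # point mode: tight tolerances, many random targets
  for (k in 1:20) {
    pp <- runif(1, 0, 0.5)
    cc <- runif(1, 0.02, 0.8)
    s <- strategy(capacity_increase = cc, conversion_fraction = pp,
                  allow_above_cap = TRUE)
    pt <- clearance_point(p, s)
    c_d <- find_capacity_for_deaths(p, pt$deaths, p = pp, mode = "point")
    c_t <- find_capacity_for_time(p, pt$tc_days, p = pp, mode = "point")
    expect_equal(c_d, cc, tolerance = 1e-4)
    expect_equal(c_t, cc, tolerance = 1e-4)
  }
  # mc-mean mode with shared common random numbers
  draws <- draw_parameters(p, n = 4000, seed = 17)
  for (pp in c(0, 0.3)) {
    s <- strategy(capacity_increase = 0.25, conversion_fraction = pp)
    Te <- total_surplus(p, s)
    target <- mean(deaths_at_clearance(
      draws$W0, Te, clearance_time(draws$W0, draws$mu, Te)))
    c_hat <- find_capacity_for_deaths(p, target, p = pp, draws = draws)
    expect_equal(c_hat, 0.25, tolerance = 1e-4)
  }
})

test_that("unattainable targets raise a bracket error with the range", {
  p <- default_params()
  expect_error(find_capacity_for_deaths(p, 50, p = 0, mode = "point",
                                        c_max = 1),
               "outside the attainable range")
  expect_error(find_capacity_for_time(p, 10000, p = 0.3, mode = "point"),
               "outside the attainable range")
})

test_that("the deaths-1000 isocline matches the published planning points", {
  p <- default_params()
  draws <- draw_parameters(p, n = 10000, seed = 20220616)
  iso <- extract_isocline(p, level = 1000, outcome = "deaths",
                          p_axis = seq(0, 0.5, by = 0.25), draws = draws)
  expect_s3_class(iso, "isocline")
  c_at <- function(pp) iso$points$c[iso$points$p == pp]
  expect_lt(abs(c_at(0) - 0.25), 0.005)
  expect_lt(abs(c_at(0.5) - 0.087), 0.005)
  # capacity requirement falls as conversion rises
  expect_true(all(diff(iso$points$c) < 0))
})

test_that("isoclines at neighbouring death levels do not cross", {
  p <- default_params()
  draws <- draw_parameters(p, n = 4000, seed = 23)
  levels <- c(500, 1000, 1500, 2000)
  curves <- lapply(levels, function(lv)
    extract_isocline(p, level = lv, outcome = "deaths",
                     p_axis = seq(0, 0.5, by = 0.25), c_max = 3,
                     draws = draws)$points)
  for (k in seq_len(length(levels) - 1)) {
    shared <- intersect(curves[[k]]$p, curves[[k + 1]]$p)
    for (pp in shared) {
      # fewer tolerated deaths demand strictly more capacity
      expect_gt(curves[[k]]$c[curves[[k]]$p == pp],
                curves[[k + 1]]$c[curves[[k + 1]]$p == pp])
    }
  }
})

test_that("an isocline through a grid point recovers that point", {
  p <- default_params()
  s <- strategy(capacity_increase = 0.3, conversion_fraction = 0.25)
  level <- clearance_point(p, s)$tc_days
  iso <- extract_isocline(p, level = level, outcome = "time",
                          p_axis = c(0.25), mode = "point")
  expect_equal(iso$points$c, 0.3, tolerance = 1e-4)
  expect_error(extract_isocline(p, level = 1, outcome = "time",
                                p_axis = c(0, 0.5), mode = "point"),
               "unattainable")
})
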