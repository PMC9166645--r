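test_that("the probability grid enumerates the step lattice", {
  expect_equal(nrow(build_grid(0.5)), 6L)
  expect_equal(nrow(build_grid(0.1)), 66L)
  expect_equal(nrow(build_grid(1)), 3L)
  g <- build_grid(0.1)
  expect_true(all(abs(rowSums(g) - 1) < 1e-9))
  expect_true(all(as.matrix(g) >= 0))
  # pure strategies are always on the lattice
  expect_true(any(g$p_cs == 1))
  expect_error(build_grid(0.3), "divide 1")
  expect_error(build_grid(0), "divide 1")
})

test_that("experiment plans encode the canned designs", {
  p2 <- experiment_plan("exp2", replications = 2)
  expect_equal(nrow(p2$grid), 101L)
  expect_true(all(p2$grid$p_visio == 0))
  expect_equal(p2$arrival_rate, 20.64)
  expect_equal(p2$share_med_transport, 1)
  expect_equal(p2$fixed_distance_km, 13.06)

  p1 <- experiment_plan("exp1", grid_step = 0.5)
  expect_equal(nrow(p1$grid), 6L)
  expect_true(any(p1$grid$p_cs == 1))  # the pure-CS comparator is on the grid

  p3 <- experiment_plan("exp3", grid_step = 1)
  expect_named(p3$strata, c("urban", "peri_urban", "remote"))
})

test_that("experiments run deterministically and carry KPI columns", {
  pop <- test_population()
  plan <- experiment_plan("exp1", grid_step = 1, replications = 2, seed = 17L)
  plan$arrival_rate <- 15
  plan$scenario_args <- list(horizon_days = 40)
  k1 <- run_experiment(plan, population = pop)
  k2 <- run_experiment(plan, population = pop)
  expect_identical(k1, k2)
  expect_equal(nrow(k1), 3L * 2L)
  expect_true(all(c("total_cost", "doctor_minutes", "volume_cs") %in% names(k1)))
})

test_that("average TC cost decreases and is convex in volume", {
  v <- c(10, 100, 1000, 10000)
  ac <- average_cost_curve(v, fixed_costs = 100, variable_cost = 10)
  expect_equal(ac[1], 20)  # 100/10 + 10
  expect_true(all(diff(ac) < 0))
  # convexity on an equally spaced grid
  vv <- seq(100, 1000, by = 100)
  aa <- average_cost_curve(vv, 129300, 35.83)
  expect_true(all(diff(diff(aa)) > 0))
  # no fixed cost: constant returns to scale
  expect_equal(average_cost_curve(v, 0, 10), rep(10, 4))
  # asymptote at the variable cost
  expect_lt(average_cost_curve(1e9, 129300, 35.83) - 35.83, 1e-3)
  expect_error(average_cost_curve(0, 1, 1), "zero volume")
})

test_that("break-even conversions follow the one-decimal day arithmetic", {
  # margin 1 makes the volume equal the fixed cost
  b1 <- break_even(2969, 2, 1, working_days = 1265)
  expect_equal(b1$volume, 2969)
  expect_equal(b1$per_day, 2.3)
  b2 <- break_even(13604, 2, 1, working_days = 1265, n_stations = 12)
  expect_equal(b2$per_day, 10.8)
  expect_equal(b2$per_day_per_station, 0.9)
  b3 <- break_even(4442, 2, 1, working_days = 1265)
  expect_equal(b3$per_day, 3.5)
  # zero fixed cost: break-even at zero volume
  expect_equal(break_even(0, 2, 1)$volume, 0)
  # non-positive margin: flagged, not an error
  b4 <- break_even(1000, 30, 40)
  expect_true(b4$never_amortized)
  expect_equal(b4$volume, Inf)
})

test_that("break-even rates fall with distance and rise without medical transport", {
  pop <- test_population()
  be <- stratified_break_even(pop, distance_strata())
  vid <- be[be$solution == "video", ]
  vid <- vid[match(c("urban", "peri_urban", "remote"), vid$stratum), ]
  # per-day rates strictly decrease from near to far strata
  expect_true(all(diff(vid$volume) < 0))
  sta <- be[be$solution == "station", ]
  sta <- sta[match(c("urban", "peri_urban", "remote"), sta$stratum), ]
  expect_true(all(diff(sta$volume) < 0))

  # all-medical-transport stratum beats a same-distance personal-transport one
  strata <- list(nursing_home = function(p) p$age > 80)
  med <- stratified_break_even(pop, strata, share_med_transport = 1,
                               fixed_distance_km = 13.06)
  per <- stratified_break_even(pop, strata, share_med_transport = 0,
                               fixed_distance_km = 13.06)
  expect_lt(med$volume[med$solution == "station"],
            per$volume[per$solution == "station"])

  # empty strata are flagged rather than dropped
  be0 <- stratified_break_even(pop, list(none = function(p) p$age > 200))
  expect_true(all(be0$empty))
})
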