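test_that("triangular parameters are canonicalized and sampled correctly", {
  expect_equal(unname(canonicalize_triangular(16.9, 29.1, 20)),
               c(16.9, 20, 29.1))
  expect_equal(unname(canonicalize_triangular(8, 9.47, 13.78)),
               c(8, 9.47, 13.78))
  expect_error(canonicalize_triangular(1, 2, NA), "three finite")

  # degenerate specification is a constant
  set.seed(1)
  expect_equal(rtriangular(5, canonicalize_triangular(5, 5, 5)), rep(5, 5))
  # sample mean of the triangular matches (a + m + b) / 3
  set.seed(2)
  x <- rtriangular(2e5, canonicalize_triangular(16.9, 29.1, 20))
  expect_lt(abs(mean(x) - (16.9 + 20 + 29.1) / 3), 0.05)
  expect_true(all(x >= 16.9 & x <= 29.1))
})

test_that("station consult times match the shifted-lognormal closed form", {
  spec <- distribution_spec("lognormal3", c(2.1888426, 0.57548749, 3.0333333))
  mu <- lnorm3_mean(2.1888426, 0.57548749, 3.0333333)
  sdv <- sqrt((exp(0.57548749^2) - 1)) * exp(2.1888426 + 0.57548749^2 / 2)
  set.seed(3)
  x <- sample_duration(spec, 1e5)
  expect_lt(abs(mean(x) - mu), 2 * sdv / sqrt(1e5))
  expect_true(all(x >= 3.0333333))
})

test_that("pathway assignment applies the over-80 video cap", {
  sc <- scenario_config(p_cs = 0.3, p_visio = 0.5, p_station = 0.2)
  # at age 85 the effective distribution is (0.4, 0.3, 0.3)
  u <- c(0.35, 0.45, 0.75, 0.85)
  expect_equal(assign_pathway(rep(85, 4), rep(TRUE, 4), sc, u = u),
               c("cs", "video", "station", "station"))
  # below 80 the configured distribution applies unchanged
  expect_equal(assign_pathway(rep(50, 4), rep(TRUE, 4), sc, u = u),
               c("video", "video", "video", "station"))
  # degenerate pure-CS scenario
  sc1 <- scenario_config(p_cs = 1, p_visio = 0, p_station = 0)
  expect_true(all(assign_pathway(c(20, 90), c(TRUE, TRUE), sc1) == "cs"))
  # ineligible agents always take the CS pathway
  expect_equal(assign_pathway(50, FALSE, sc), "cs")
})

test_that("a pure-CS scenario produces no transfers, nurse time or avoided travel", {
  pop <- test_population()
  r <- run_replication(small_scenario(p_cs = 1, p_visio = 0, p_station = 0),
                       seed = 4L, population = pop)
  expect_equal(r$n_transfers, 0)
  expect_equal(r$nurse_minutes, 0)
  expect_equal(r$travel_minutes_avoided, 0)
  expect_equal(unname(r$volumes), unname(c(r$assigned["cs"], 0, 0)))
})

test_that("station quota and nurse sick leave redirect agents to a CS", {
  pop <- test_population()
  sc <- small_scenario(p_cs = 0, p_visio = 0, p_station = 1,
                       n_stations = 1, station_daily_capacity = 7,
                       arrival_rate = 30)
  r <- run_replication(sc, seed = 5L, population = pop, keep_events = TRUE)
  ev <- r$events
  done_per_day <- tapply(ev$station_completed, ev$day, sum)
  expect_true(all(done_per_day <= 7))
  # redirected agents attend a CS and are charged the round trip
  tr <- ev[ev$station_transfer, ]
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$attends_cs))
  expect_equal(r$n_transfers, sum(ev$station_transfer) + sum(ev$video_followup))
})

test_that("KPI accounting is conserved against the event log", {
  pop <- test_population()
  sc <- small_scenario(p_cs = 0.5, p_visio = 0.3, p_station = 0.2)
  r <- run_replication(sc, seed = 6L, population = pop, keep_events = TRUE)
  ev <- r$events
  # volume conservation
  expect_equal(r$arrivals, nrow(ev))
  expect_equal(unname(r$assigned["cs"] + r$assigned["video"] +
                        r$assigned["station"]), r$arrivals)
  expect_equal(unname(r$volumes["cs"]),
               unname(r$assigned["cs"]) + sum(ev$video_followup) +
                 sum(ev$station_transfer))
  # resource-minute audit: report equals the event-log replay exactly
  expect_equal(r$doctor_minutes, sum(ev$doctor_min))
  expect_equal(r$admin_minutes, sum(ev$admin_min))
  expect_equal(r$nurse_minutes, sum(ev$nurse_min))
  # travel accounting: travel + avoided equals the pure-CS charge per agent
  rt <- 2 * ev$travel_time_min
  travel <- ifelse(ev$attends_cs, rt, 0)
  avoided <- ifelse((ev$pathway == "video" & !ev$video_followup) |
                      ev$station_completed, rt, 0)
  expect_equal(r$total_travel_minutes, sum(travel))
  expect_equal(r$travel_minutes_avoided, sum(avoided))
  # video follow-up agents both consult remotely and travel; everyone else
  # contributes exactly one of the two terms
  full <- travel + avoided
  expect_true(all(full[!ev$video_followup & !(ev$pathway == "station" &
    !ev$station_completed & !ev$attends_cs)] >= 0))
  expect_equal(sum((travel + avoided)[!ev$video_followup]),
               sum(rt[!ev$video_followup]))
})

test_that("replications are deterministic given the seed", {
  pop <- test_population()
  sc <- small_scenario(p_cs = 0.6, p_visio = 0.3, p_station = 0.1)
  r1 <- run_replication(sc, seed = 9L, population = pop)
  r2 <- run_replication(sc, seed = 9L, population = pop)
  expect_identical(kpi_vector_public(r1), kpi_vector_public(r2))
  # constant durations + same stream: bit-identical by construction
  const <- lapply(default_duration_specs(),
                  function(s) distribution_spec("constant", 5))
  scc <- small_scenario(duration_specs = const)
  expect_identical(kpi_vector_public(run_replication(scc, 10L, pop)),
                   kpi_vector_public(run_replication(scc, 10L, pop)))
})

test_that("more video consultations reduce doctor minutes on paired seeds", {
  pop <- test_population()
  r_cs <- run_replication(small_scenario(p_cs = 1, p_visio = 0, p_station = 0),
                          seed = 12L, population = pop)
  r_vid <- run_replication(small_scenario(p_cs = 0, p_visio = 1, p_station = 0),
                           seed = 12L, population = pop)
  expect_lt(r_vid$doctor_minutes, r_cs$doctor_minutes)
})

test_that("replication summaries average the stored KPI vectors", {
  pop <- test_population()
  sc <- small_scenario(replications = 3)
  reports <- simulate_scenario(sc, pop)
  s <- summarize_replications(reports)
  m <- sapply(reports, function(r) r$total_cost)
  expect_equal(s$mean[s$kpi == "total_cost"], mean(m))
  # identical reports: zero half-widths
  s0 <- summarize_replications(list(reports[[1]], reports[[1]]))
  expect_true(all(s0$ci_half_width == 0))
  expect_error(summarize_replications(reports[1]), "at least 2")
})
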