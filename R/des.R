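# Discrete-event simulation of three consultation pathways:
#   1. physical consultation (CS): patient travels, doctor consult, admin;
#   2. video teleconsultation: shorter doctor consult, admin (longer for
#      new patients), doctor registration for a first TC, and a possible
#      follow-up CS within 7 days (counted as a transfer);
#   3. telehealth station: nurse sets up and closes the session, doctor
#      consult (shifted lognormal), admin; a sick nurse or an exhausted
#      daily station quota redirects the agent to a CS (transfer).
#
# Days are the scheduling unit: arrivals are daily Poisson draws, station
# quotas reset each day, within-day ordering is arrival order. No
# waiting-time KPI exists, so sub-day interleaving is immaterial;
# 1 day = 1440 minutes for horizon arithmetic (1265 days = 1,821,600 min).

#' Duration distribution specification
#'
#' @param family one of "triangular", "lognormal3", "constant", "poisson",
#'   "bernoulli".
#' @param params family-specific parameters. Triangular parameters are
#'   canonicalized (sorted) to (min, mode, max); `lognormal3` takes
#'   (meanlog, sdlog, shift).
#' @return an object of class `distribution_spec`.
#' @export
distribution_spec <- function(family, params) {
  family <- match.arg(family, c("triangular", "lognormal3", "constant",
                                "poisson", "bernoulli"))
  params <- as.numeric(params)
  if (family == "triangular") {
    params <- canonicalize_triangular(params[1L], params[2L], params[3L])
  }
  if (family == "lognormal3" && params[2L] <= 0) {
    stop("lognormal3 sdlog must be > 0", call. = FALSE)
  }
  if (family == "bernoulli") assert_prob(params[1L], "bernoulli p")
  structure(list(family = family, params = params),
            class = "distribution_spec")
}

#' Sample durations from a distribution specification
#' @param spec a [distribution_spec()].
#' @param n number of draws.
#' @return numeric vector of `n` non-negative draws.
#' @export
sample_duration <- function(spec, n) {
  if (n == 0L) return(numeric(0))
  p <- spec$params
  out <- switch(spec$family,
    triangular = rtriangular(n, p),
    lognormal3 = rlnorm3(n, p[1L], p[2L], p[3L]),
    constant = rep(p[1L], n),
    poisson = stats::rpois(n, p[1L]),
    bernoulli = stats::rbinom(n, 1L, p[1L])
  )
  pmax(out, 0)
}

#' Mean of a distribution specification
#' @param spec a [distribution_spec()].
#' @return the theoretical mean.
#' @export
spec_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    triangular = sum(p) / 3,
    lognormal3 = lnorm3_mean(p[1L], p[2L], p[3L]),
    constant = p[1L],
    poisson = p[1L],
    bernoulli = p[1L]
  )
}

default_duration_specs <- function() {
  tri <- function(a, b, c) distribution_spec("triangular", c(a, b, c))
  list(
    cs_consult = tri(16.9, 29.1, 20),
    cs_admin = tri(1, 2, 1.5),
    video_consult = tri(8, 9.47, 13.78),
    video_admin = tri(1, 2, 1.5),
    video_admin_new = tri(8, 10, 9),
    video_registration = tri(1, 2, 1.5),
    station_prep = tri(8, 12, 10),
    station_consult = distribution_spec("lognormal3",
                                        c(2.1888426, 0.57548749, 3.0333333)),
    station_close = tri(3, 7, 5),
    station_admin = tri(2.5, 4.5, 3.5),
    station_admin_new = tri(10, 15, 12.5)
  )
}

# ICD-10 chapters and care units ever observed for TC patients: agents
# outside these always take the CS pathway.
default_eligibility <- function() {
  icd <- icd10_table(); cu <- care_unit_table()
  list(icd10_chapter = icd$category[icd$tc > 0],
       care_unit = cu$category[cu$tc > 0])
}

#' Simulation scenario configuration
#'
#' Defaults are the base-case calibration: pathway probabilities
#' (0.9507, 0.0362, 0.0131), Poisson(89.953782) daily arrivals, 12 stations
#' with a daily capacity of 7 TCs each, a 5-year horizon of 1265 working
#' days (1,821,600 minutes), 20 replications, nurse sick-leave probability
#' 0.05 per station team, and the consult/admin duration set of the source
#' calibration.
#'
#' @param p_cs,p_visio,p_station pathway probabilities; must sum to 1. For
#'   agents older than 80 the video probability is capped at 0.3, the excess
#'   being split equally between the CS and station pathways.
#' @param arrival_rate mean daily arrivals.
#' @param n_stations,teams_per_station,station_daily_capacity telehealth
#'   station fleet and per-station daily TC quota.
#' @param share_med_transport medically-transported share used in the cost
#'   KPI.
#' @param population_filter optional predicate on the population data.frame
#'   (e.g. `function(p) p$age > 80`).
#' @param fixed_distance_km optional fixed one-way distance overriding the
#'   population's (e.g. 13.06 for the nursing-home scenario).
#' @param horizon_days,minutes_per_day simulated horizon.
#' @param replications number of replications.
#' @param seed root seed; replication r uses a seed derived from it.
#' @param duration_specs named list of [distribution_spec()]s.
#' @param p_first_tc_patient probability a TC patient is a first-time TC
#'   patient (patient level).
#' @param p_first_tc conversion factor 1 / (TCs per patient); also the
#'   probability that a video TC requires doctor registration.
#' @param p_cs_after_video probability of a follow-up CS within 7 days of a
#'   video TC.
#' @param p_nurse_sick_base nurse sick-leave probability, divided by the
#'   number of teams per station.
#' @param eligibility list of eligible `icd10_chapter` and `care_unit`
#'   categories; ineligible agents always take the CS pathway.
#' @param cost_config a [cost_inputs()] object for the cost KPI.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(p_cs = 0.9507, p_visio = 0.0362,
                            p_station = 0.0131,
                            arrival_rate = 89.953782,
                            n_stations = 12, teams_per_station = 1,
                            station_daily_capacity = 7,
                            share_med_transport = 0.36,
                            population_filter = NULL,
                            fixed_distance_km = NULL,
                            horizon_days = 1265, minutes_per_day = 1440,
                            replications = 20, seed = 1L,
                            duration_specs = default_duration_specs(),
                            p_first_tc_patient = 0.2368,
                            p_first_tc = 0.8512,
                            p_cs_after_video = 0.0672,
                            p_nurse_sick_base = 0.05,
                            eligibility = default_eligibility(),
                            cost_config = cost_inputs()) {
  assert_freq(c(p_cs, p_visio, p_station), "pathway probabilities")
  assert_pos(arrival_rate, "arrival_rate", strict = TRUE)
  assert_pos(horizon_days, "horizon_days", strict = TRUE)
  assert_prob(p_first_tc_patient, "p_first_tc_patient")
  assert_prob(p_first_tc, "p_first_tc")
  assert_prob(p_cs_after_video, "p_cs_after_video")
  assert_prob(p_nurse_sick_base, "p_nurse_sick_base")
  if (!is.null(fixed_distance_km)) assert_pos(fixed_distance_km,
                                              "fixed_distance_km")
  structure(list(
    p_cs = p_cs, p_visio = p_visio, p_station = p_station,
    arrival_rate = arrival_rate, n_stations = n_stations,
    teams_per_station = teams_per_station,
    station_daily_capacity = station_daily_capacity,
    share_med_transport = share_med_transport,
    population_filter = population_filter,
    fixed_distance_km = fixed_distance_km,
    horizon_days = as.integer(horizon_days),
    minutes_per_day = minutes_per_day,
    replications = as.integer(replications), seed = as.integer(seed),
    duration_specs = duration_specs,
    p_first_tc_patient = p_first_tc_patient, p_first_tc = p_first_tc,
    p_cs_after_video = p_cs_after_video,
    p_nurse_sick_base = p_nurse_sick_base,
    eligibility = eligibility,
    cost_config = cost_config
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: (P_CS, P_video, P_station) = (%.4f, %.4f, %.4f)\n",
              x$p_cs, x$p_visio, x$p_station))
  cat(sprintf("  %.2f arrivals/day over %d days (%s minutes), %d stations x %d TC/day\n",
              x$arrival_rate, x$horizon_days,
              format(x$horizon_days * x$minutes_per_day, big.mark = ","),
              x$n_stations, x$station_daily_capacity))
  invisible(x)
}

#' Assign consultation pathways
#'
#' Vectorised pathway draw. For agents older than 80, when the configured
#' video probability exceeds 0.3 it is capped there and the excess is split
#' equally between the CS and station pathways. Ineligible agents always
#' take the CS pathway.
#'
#' @param age agent ages.
#' @param eligible logical vector (same length).
#' @param scenario a [scenario_config()].
#' @param u optional uniform draws (for testing); defaults to `runif`.
#' @return character vector in `c("cs", "video", "station")`.
#' @export
assign_pathway <- function(age, eligible, scenario, u = NULL) {
  n <- length(age)
  if (is.null(u)) u <- stats::runif(n)
  p_cs <- rep(scenario$p_cs, n)
  p_visio <- rep(scenario$p_visio, n)
  if (scenario$p_visio > 0.3) {
    old <- age > 80
    excess <- scenario$p_visio - 0.3
    p_visio[old] <- 0.3
    p_cs[old] <- scenario$p_cs + excess / 2
    # the station share absorbs the other half (implied by summation to 1)
  }
  path <- rep("cs", n)
  path[u >= p_cs & u < p_cs + p_visio] <- "video"
  path[u >= p_cs + p_visio] <- "station"
  path[!eligible] <- "cs"
  path
}

# per-day arrival-order rank within a subset of agents
day_rank <- function(day) {
  if (!length(day)) return(integer(0))
  stats::ave(seq_along(day), day, FUN = seq_along)
}

#' Run one simulation replication
#'
#' Simulates `horizon_days` days: daily Poisson arrivals resampled from the
#' population, pathway assignment, station quota and nurse sick-leave
#' redirects, duration draws, and KPI accumulation. Equipment fixed costs
#' are charged once per replication at their 5-year totals; per-type average
#' cost is (allocated fixed + variable) / completed volume. Deterministic
#' given `seed`; each stochastic decision category draws from its own
#' sub-stream, so adding a KPI never perturbs existing draws.
#'
#' @param scenario a [scenario_config()].
#' @param seed replication seed.
#' @param population a `patient_population` to resample agents from.
#' @param keep_events if TRUE, attach the per-agent event log (for audits).
#' @return an object of class `kpi_report`.
#' @export
run_replication <- function(scenario, seed, population,
                            keep_events = FALSE) {
  if (scenario$horizon_days <= 0) stop("zero-length horizon", call. = FALSE)
  ds <- scenario$duration_specs
  agents <- sample_agents(NULL, scenario$horizon_days, scenario$arrival_rate,
                          seed = derive_seed(seed, "stream"),
                          population = population,
                          filter = scenario$population_filter)
  n <- nrow(agents)
  if (!is.null(scenario$fixed_distance_km)) {
    agents$distance_km <- rep(scenario$fixed_distance_km, n)
    agents$travel_time_min <- agents$distance_km /
      (attr(population, "params")$travel_speed %||% 0.9)
  }
  eligible <- agents$icd10_chapter %in% scenario$eligibility$icd10_chapter &
    agents$care_unit %in% scenario$eligibility$care_unit

  set.seed(derive_seed(seed, "pathway"))
  path <- assign_pathway(agents$age, eligible, scenario)
  is_cs <- path == "cs"; is_video <- path == "video"
  is_station <- path == "station"

  # new-patient flag at the consult level
  set.seed(derive_seed(seed, "new_flag"))
  p_new <- scenario$p_first_tc_patient * scenario$p_first_tc
  new_flag <- stats::runif(n) < p_new

  # video pathway: follow-up CS within 7 days (transfer), registration
  set.seed(derive_seed(seed, "video_transfer"))
  video_followup <- is_video & stats::runif(n) < scenario$p_cs_after_video
  set.seed(derive_seed(seed, "video_registration"))
  video_reg <- is_video & stats::runif(n) < scenario$p_first_tc

  # station pathway: nurse sick leave, then the daily quota
  set.seed(derive_seed(seed, "nurse_sick"))
  p_sick <- scenario$p_nurse_sick_base / scenario$teams_per_station
  sick <- is_station & stats::runif(n) < p_sick
  station_try <- which(is_station & !sick)
  rk <- day_rank(agents$day[station_try])
  fleet_cap <- scenario$n_stations * scenario$station_daily_capacity
  station_done <- station_try[rk <= fleet_cap]
  station_over <- station_try[rk > fleet_cap]
  station_completed <- rep(FALSE, n); station_completed[station_done] <- TRUE
  station_transfer <- (is_station & sick)
  station_transfer[station_over] <- TRUE

  # physical attendance: assigned CS, video follow-ups, station redirects
  attends_cs <- is_cs | video_followup | station_transfer
  n_transfers <- sum(video_followup) + sum(station_transfer)

  # duration draws, one sub-stream per category
  draw <- function(label, spec, idx) {
    k <- sum(idx)
    out <- numeric(n)
    if (k) {
      set.seed(derive_seed(seed, label))
      out[idx] <- sample_duration(spec, k)
    }
    out
  }
  dur_cs_consult <- draw("dur_cs_consult", ds$cs_consult, attends_cs)
  dur_cs_admin <- draw("dur_cs_admin", ds$cs_admin, attends_cs)
  dur_video_consult <- draw("dur_video_consult", ds$video_consult, is_video)
  dur_video_admin <- draw("dur_video_admin", ds$video_admin,
                          is_video & !new_flag)
  dur_video_admin_new <- draw("dur_video_admin_new", ds$video_admin_new,
                              is_video & new_flag)
  dur_video_reg <- draw("dur_video_reg", ds$video_registration, video_reg)
  dur_station_prep <- draw("dur_station_prep", ds$station_prep,
                           station_completed)
  dur_station_consult <- draw("dur_station_consult", ds$station_consult,
                              station_completed)
  dur_station_close <- draw("dur_station_close", ds$station_close,
                            station_completed)
  dur_station_admin <- draw("dur_station_admin", ds$station_admin,
                            station_completed & !new_flag)
  dur_station_admin_new <- draw("dur_station_admin_new",
                                ds$station_admin_new,
                                station_completed & new_flag)

  doctor_minutes <- sum(dur_cs_consult) + sum(dur_video_consult) +
    sum(dur_video_reg) + sum(dur_station_consult)
  admin_minutes <- sum(dur_cs_admin) + sum(dur_video_admin) +
    sum(dur_video_admin_new) + sum(dur_station_admin) +
    sum(dur_station_admin_new)
  nurse_minutes <- sum(dur_station_prep) + sum(dur_station_close)

  round_trip <- 2 * agents$travel_time_min
  total_travel <- sum(round_trip[attends_cs])
  # avoided travel counts completed TCs whose agent did not travel
  avoided <- sum(round_trip[(is_video & !video_followup) | station_completed])

  # ---- cost KPI ----
  ci <- scenario$cost_config
  ci_run <- modify_inputs(ci, list(share_med_transport =
                                     scenario$share_med_transport))
  trip_km <- 2 * agents$distance_km
  transport <- numeric(n)
  transport[attends_cs] <- ci_run$share_med_transport *
    medical_transport_cost(trip_km[attends_cs], ci_run) +
    (1 - ci_run$share_med_transport) *
    nonmedical_transport_cost(trip_km[attends_cs], ci_run)
  cost_cs_bucket <- sum(attends_cs) * ci$consult_fee + sum(transport)
  cost_video_var <- sum(is_video) * ci$consult_fee
  cost_station_var <- sum(station_completed) * (ci$consult_fee + ci$nurse_fee)

  fx <- fixed_cost_totals(ci)
  vol_cs <- sum(attends_cs)
  vol_video <- sum(is_video)
  vol_station <- sum(station_completed)
  total_cost <- cost_cs_bucket + cost_video_var + cost_station_var +
    (if (scenario$p_visio > 0) fx$video else 0) +
    (if (scenario$p_station > 0) fx$station else 0)
  cost_per_type <- c(
    cs = if (vol_cs) cost_cs_bucket / vol_cs else NA_real_,
    video = if (vol_video) (cost_video_var + fx$video) / vol_video else NA_real_,
    station = if (vol_station)
      (cost_station_var + fx$station) / vol_station else NA_real_
  )

  report <- structure(list(
    total_cost = total_cost,
    cost_per_type = cost_per_type,
    doctor_minutes = doctor_minutes,
    admin_minutes = admin_minutes,
    nurse_minutes = nurse_minutes,
    n_transfers = n_transfers,
    volumes = c(cs = vol_cs, video = vol_video, station = vol_station),
    total_travel_minutes = total_travel,
    travel_minutes_avoided = avoided,
    arrivals = n,
    assigned = c(cs = sum(is_cs), video = sum(is_video),
                 station = sum(is_station)),
    fixed_costs = fx,
    seed = seed
  ), class = "kpi_report")
  if (keep_events) {
    report$events <- data.frame(
      day = agents$day, pathway = path, eligible = eligible,
      travel_time_min = agents$travel_time_min,
      attends_cs = attends_cs, video_followup = video_followup,
      station_completed = station_completed,
      station_transfer = station_transfer,
      doctor_min = dur_cs_consult + dur_video_consult + dur_video_reg +
        dur_station_consult,
      admin_min = dur_cs_admin + dur_video_admin + dur_video_admin_new +
        dur_station_admin + dur_station_admin_new,
      nurse_min = dur_station_prep + dur_station_close,
      transport_cost = transport
    )
  }
  report
}

#' @export
print.kpi_report <- function(x, ...) {
  cat(sprintf("KPI report: %d arrivals, volumes CS/video/station = %d/%d/%d, %d transfers\n",
              x$arrivals, x$volumes[["cs"]], x$volumes[["video"]],
              x$volumes[["station"]], x$n_transfers))
  cat(sprintf("  total cost %.0f EUR; doctor/admin/nurse minutes %.0f/%.0f/%.0f\n",
              x$total_cost, x$doctor_minutes, x$admin_minutes,
              x$nurse_minutes))
  invisible(x)
}

# flatten a kpi_report to a named numeric vector
kpi_vector <- function(report) {
  c(total_cost = report$total_cost,
    cost_per_cs = report$cost_per_type[["cs"]],
    cost_per_video = report$cost_per_type[["video"]],
    cost_per_station = report$cost_per_type[["station"]],
    doctor_minutes = report$doctor_minutes,
    admin_minutes = report$admin_minutes,
    nurse_minutes = report$nurse_minutes,
    n_transfers = report$n_transfers,
    volume_cs = report$volumes[["cs"]],
    volume_video = report$volumes[["video"]],
    volume_station = report$volumes[["station"]],
    total_travel_minutes = report$total_travel_minutes,
    travel_minutes_avoided = report$travel_minutes_avoided,
    arrivals = report$arrivals)
}

#' Run all replications of a scenario
#'
#' @param scenario a [scenario_config()].
#' @param population a `patient_population`.
#' @param replications overrides `scenario$replications` when given.
#' @return list of `kpi_report`s; replication r uses a seed derived from
#'   the scenario root seed and r.
#' @export
simulate_scenario <- function(scenario, population, replications = NULL) {
  reps <- replications %||% scenario$replications
  lapply(seq_len(reps), function(r) {
    run_replication(scenario, derive_seed(scenario$seed, paste0("rep", r)),
                    population)
  })
}

#' Summarise replications
#'
#' @param reports list of `kpi_report`s (at least 2).
#' @return a `data.frame` with one row per KPI: mean, sd and t-based 95%
#'   confidence half-width across replications.
#' @export
summarize_replications <- function(reports) {
  if (length(reports) < 2L) {
    stop("need at least 2 replications to summarise", call. = FALSE)
  }
  m <- do.call(rbind, lapply(reports, kpi_vector))
  n <- nrow(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  hw <- stats::qt(0.975, df = n - 1L) * sdv / sqrt(n)
  data.frame(kpi = colnames(m), mean = unname(mu), sd = unname(sdv),
             ci_half_width = unname(hw), stringsAsFactors = FALSE)
}
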