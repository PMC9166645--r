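# Scenario sweeps, average-cost-versus-volume curves and break-even
# amortization levels.

#' Five-year fixed-cost totals of the two teleconsultation solutions
#'
#' Video solution: software over 60 months for every user plus the one-off
#' camera/headphone. Station fleet: the depreciable part (purchase,
#' installation, training) consumed over 60 months, maintenance over 60
#' months, consumables over 5 years and the one-off medical equipment of the
#' full stations.
#'
#' @param inputs a [cost_inputs()] object.
#' @return list with `video` and `station` totals (euros).
#' @export
fixed_cost_totals <- function(inputs = cost_inputs()) {
  horizon_months <- 60
  n_full <- round(inputs$n_stations * inputs$share_full_stations)
  n_wallet <- inputs$n_stations - n_full
  m <- monthly_equipment_costs(inputs)
  station <- (n_full * m$device_depreciable +
                n_wallet * m$wallet_depreciable) * horizon_months +
    inputs$n_stations * inputs$maintenance_monthly * horizon_months +
    inputs$n_stations * inputs$consumables_annual * horizon_months / 12 +
    n_full * inputs$med_equipment_per_station
  video <- inputs$n_doctors * inputs$software_monthly_per_user *
    horizon_months + inputs$n_doctors * inputs$headphone_per_user
  list(video = video, station = station)
}

#' Enumerate the pathway-probability grid
#'
#' All non-negative triples (P_CS, P_video, P_station) on the step lattice
#' summing to one.
#'
#' @param step lattice step; `1/step` must be an integer (e.g. 0.1, 0.01).
#' @return a `data.frame` with columns `p_cs`, `p_visio`, `p_station`;
#'   `(n+1)(n+2)/2` rows for `n = 1/step`.
#' @export
build_grid <- function(step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step > 1 ||
      abs(1 / step - round(1 / step)) > 1e-9) {
    stop("'step' must divide 1 exactly (e.g. 0.5, 0.1, 0.01)", call. = FALSE)
  }
  n <- round(1 / step)
  rows <- list()
  for (i in 0:n) for (j in 0:(n - i)) {
    rows[[length(rows) + 1L]] <- c(i, j, n - i - j)
  }
  g <- do.call(rbind, rows) * step
  data.frame(p_cs = g[, 1L], p_visio = g[, 2L], p_station = g[, 3L])
}

#' Experiment plan
#'
#' The four canned designs: `base` (the observed intensity of use, a
#' validation run), `exp1` (full probability grid, whole population),
#' `exp2` (elderly nursing-home population: video disabled, P_CS swept
#' 0..1 by 0.01, all-medical transport, fixed 13.06 km distance, 20.64
#' arrivals/day) and `exp3` (the grid within distance strata <20, 20-50,
#' >=50 km).
#'
#' @param experiment_id one of "base", "exp1", "exp2", "exp3".
#' @param grid_step lattice step for exp1/exp3 grids.
#' @param replications replications per scenario.
#' @param seed root seed.
#' @param arrival_rate,share_med_transport,fixed_distance_km,population_filter
#'   overrides of the design defaults.
#' @param scenario_args extra arguments passed to [scenario_config()].
#' @return an object of class `experiment_plan`.
#' @export
experiment_plan <- function(experiment_id = c("base", "exp1", "exp2", "exp3"),
                            grid_step = 0.1, replications = 20, seed = 1L,
                            arrival_rate = NULL, share_med_transport = NULL,
                            fixed_distance_km = NULL,
                            population_filter = NULL,
                            scenario_args = list()) {
  experiment_id <- match.arg(experiment_id)
  if (experiment_id == "base") {
    grid <- data.frame(p_cs = 0.9507, p_visio = 0.0362, p_station = 0.0131)
  } else if (experiment_id == "exp2") {
    p_cs <- seq(0, 1, by = 0.01)
    grid <- data.frame(p_cs = p_cs, p_visio = 0, p_station = 1 - p_cs)
    arrival_rate <- arrival_rate %||% 20.64
    share_med_transport <- share_med_transport %||% 1
    fixed_distance_km <- fixed_distance_km %||% 13.06
    population_filter <- population_filter %||% function(p) p$age > 80
  } else {
    grid <- build_grid(grid_step)
  }
  if (any(abs(rowSums(grid) - 1) > 1e-9)) {
    stop("probability grid rows must sum to 1", call. = FALSE)
  }
  strata <- NULL
  if (experiment_id == "exp3") {
    strata <- list(
      urban = function(p) p$distance_km < 20,
      peri_urban = function(p) p$distance_km >= 20 & p$distance_km < 50,
      remote = function(p) p$distance_km >= 50
    )
  }
  structure(list(
    experiment_id = experiment_id, grid = grid,
    replications = as.integer(replications), seed = as.integer(seed),
    arrival_rate = arrival_rate %||% 89.953782,
    share_med_transport = share_med_transport %||% 0.36,
    fixed_distance_km = fixed_distance_km,
    population_filter = population_filter,
    strata = strata,
    scenario_args = scenario_args
  ), class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("Experiment '%s': %d scenario(s) x %d replication(s)\n",
              x$experiment_id, nrow(x$grid), x$replications))
  invisible(x)
}

plan_scenario <- function(plan, row, filter = NULL) {
  args <- c(list(
    p_cs = plan$grid$p_cs[row], p_visio = plan$grid$p_visio[row],
    p_station = plan$grid$p_station[row],
    arrival_rate = plan$arrival_rate,
    share_med_transport = plan$share_med_transport,
    fixed_distance_km = plan$fixed_distance_km,
    population_filter = filter %||% plan$population_filter,
    replications = plan$replications,
    seed = plan$seed
  ), plan$scenario_args)
  do.call(scenario_config, args)
}

#' Run an experiment plan
#'
#' Runs the simulation for every scenario of the plan (and, for `exp3`,
#' every distance stratum), one row per scenario x replication. Deterministic
#' given the plan seed.
#'
#' @param plan an [experiment_plan()].
#' @param population a `patient_population` (generated from defaults with
#'   the plan seed when omitted).
#' @return a `data.frame` with scenario identifiers, the probability triple,
#'   the stratum (if any), the replication index and the KPI columns.
#' @export
run_experiment <- function(plan, population = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (is.null(population)) {
    population <- generate_population(population_params(seed = plan$seed))
  }
  strata <- plan$strata %||% list(all = NULL)
  out <- list()
  for (snm in names(strata)) {
    for (row in seq_len(nrow(plan$grid))) {
      sc <- plan_scenario(plan, row, filter = strata[[snm]])
      reports <- simulate_scenario(sc, population)
      for (r in seq_along(reports)) {
        out[[length(out) + 1L]] <- data.frame(
          experiment = plan$experiment_id, stratum = snm, scenario = row,
          p_cs = sc$p_cs, p_visio = sc$p_visio, p_station = sc$p_station,
          replication = r, t(kpi_vector(reports[[r]])),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average cost per teleconsultation at a given volume
#'
#' `fixed_costs / volume + variable_cost`: strictly decreasing and convex
#' in volume, reflecting the amortisation of the initial investment.
#'
#' @param volumes completed TC volumes (> 0).
#' @param fixed_costs total fixed cost (euros).
#' @param variable_cost variable cost per TC (euros).
#' @return euros per TC at each volume.
#' @export
average_cost_curve <- function(volumes, fixed_costs, variable_cost) {
  if (any(volumes <= 0)) {
    stop("average cost is undefined at zero volume", call. = FALSE)
  }
  fixed_costs / volumes + variable_cost
}

#' Break-even amortization level
#'
#' Minimum TC volume at which the average cost per TC (fixed cost spread
#' over the volume plus the variable cost) equals the reference average
#' cost per physical consultation:
#' `volume = ceiling(fixed_costs / (reference_cs_cost - variable_cost))`.
#'
#' @param fixed_costs total fixed cost over the horizon (euros).
#' @param reference_cs_cost average cost per physical consultation (euros).
#' @param variable_cost variable cost per TC (euros).
#' @param working_days working days in the horizon (1265 = 5 x 253).
#' @param n_stations station count for per-station rates.
#' @return an object of class `break_even_result`: `volume`, `per_day`,
#'   `per_day_per_station` (both rounded to one decimal) and
#'   `never_amortized`. A non-positive margin is flagged, not an error.
#' @export
break_even <- function(fixed_costs, reference_cs_cost, variable_cost,
                       working_days = 1265, n_stations = 12) {
  margin <- reference_cs_cost - variable_cost
  if (margin <= 0) {
    return(structure(list(volume = Inf, per_day = Inf,
                          per_day_per_station = Inf, margin = margin,
                          never_amortized = TRUE),
                     class = "break_even_result"))
  }
  volume <- if (fixed_costs <= 0) 0 else ceiling(fixed_costs / margin)
  structure(list(
    volume = volume,
    per_day = round(volume / working_days, 1),
    per_day_per_station = round(volume / (working_days * n_stations), 1),
    margin = margin,
    never_amortized = FALSE
  ), class = "break_even_result")
}

#' @export
print.break_even_result <- function(x, ...) {
  if (x$never_amortized) {
    cat("Break-even: never amortized (non-positive margin",
        sprintf("%.2f EUR)\n", x$margin))
  } else {
    cat(sprintf("Break-even: %s TCs (%.1f/day; %.1f/station/day)\n",
                format(x$volume, big.mark = ","), x$per_day,
                x$per_day_per_station))
  }
  invisible(x)
}

# closed-form per-consultation reference and variable costs on a population
consultation_unit_costs <- function(pop, inputs, share_med_transport = NULL,
                                    p_cs_after_video = 0.0672) {
  share <- share_med_transport %||% inputs$share_med_transport
  trip <- 2 * pop$distance_km
  transport <- share * medical_transport_cost(trip, inputs) +
    (1 - share) * nonmedical_transport_cost(trip, inputs)
  ref_cs <- inputs$consult_fee + mean(transport)
  list(
    ref_cs = ref_cs,
    # a video TC costs its fee plus, with the follow-up probability, a CS
    video = inputs$consult_fee + p_cs_after_video * ref_cs,
    station = inputs$consult_fee + inputs$nurse_fee
  )
}

#' Break-even levels for both teleconsultation solutions
#'
#' Computes the reference per-CS cost and per-TC variable costs from a
#' population (closed form: consultation fee plus mean round-trip transport
#' cost for a CS) and the 5-year fixed-cost totals, then the break-even
#' volume and per-day rates for the videoconferencing solution and the
#' station fleet.
#'
#' @param pop a `patient_population` (or filtered subset).
#' @param inputs a [cost_inputs()].
#' @param share_med_transport override of the medically-transported share.
#' @param working_days horizon working days.
#' @return a `data.frame` with one row per solution (`video`, `station`).
#' @export
break_even_levels <- function(pop, inputs = cost_inputs(),
                              share_med_transport = NULL,
                              working_days = 1265) {
  uc <- consultation_unit_costs(pop, inputs, share_med_transport)
  fx <- fixed_cost_totals(inputs)
  b_video <- break_even(fx$video, uc$ref_cs, uc$video, working_days,
                        inputs$n_stations)
  b_station <- break_even(fx$station, uc$ref_cs, uc$station, working_days,
                          inputs$n_stations)
  data.frame(
    solution = c("video", "station"),
    fixed_cost = c(fx$video, fx$station),
    reference_cs_cost = uc$ref_cs,
    variable_cost = c(uc$video, uc$station),
    volume = c(b_video$volume, b_station$volume),
    per_day = c(b_video$per_day, b_station$per_day),
    per_day_per_station = c(NA_real_, b_station$per_day_per_station),
    never_amortized = c(b_video$never_amortized, b_station$never_amortized),
    stringsAsFactors = FALSE
  )
}

#' Break-even levels per population stratum
#'
#' Applies [break_even_levels()] within each stratum of the population.
#' Empty strata are flagged, not dropped.
#'
#' @param pop a `patient_population`.
#' @param strata named list of predicates on the population data.frame.
#' @param inputs a [cost_inputs()].
#' @param share_med_transport optional per-stratum override: a single value
#'   or a named list keyed by stratum.
#' @param fixed_distance_km optional per-stratum fixed distance (named list
#'   or single value), e.g. 13.06 for nursing homes.
#' @param working_days horizon working days.
#' @return a `data.frame`, two rows (video/station) per stratum, with an
#'   `empty` flag for strata containing no patients.
#' @export
stratified_break_even <- function(pop, strata, inputs = cost_inputs(),
                                  share_med_transport = NULL,
                                  fixed_distance_km = NULL,
                                  working_days = 1265) {
  out <- list()
  for (snm in names(strata)) {
    sub <- pop[strata[[snm]](pop), , drop = FALSE]
    if (!nrow(sub)) {
      out[[snm]] <- data.frame(stratum = snm, solution = c("video", "station"),
                               fixed_cost = NA_real_,
                               reference_cs_cost = NA_real_,
                               variable_cost = NA_real_, volume = NA_real_,
                               per_day = NA_real_,
                               per_day_per_station = NA_real_,
                               never_amortized = NA, empty = TRUE,
                               stringsAsFactors = FALSE)
      next
    }
    smt <- if (is.list(share_med_transport)) share_med_transport[[snm]]
           else share_med_transport
    fdk <- if (is.list(fixed_distance_km)) fixed_distance_km[[snm]]
           else fixed_distance_km
    if (!is.null(fdk)) sub$distance_km <- fdk
    bl <- break_even_levels(sub, inputs, smt, working_days)
    bl$stratum <- snm
    bl$empty <- FALSE
    out[[snm]] <- bl[, c("stratum", setdiff(names(bl), "stratum"))]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distance strata used by the geographic experiment
#' @return named list of predicates (urban < 20 km, peri-urban 20-50 km,
#'   remote >= 50 km).
#' @export
distance_strata <- function() {
  list(
    urban = function(p) p$distance_km < 20,
    peri_urban = function(p) p$distance_km >= 20 & p$distance_km < 50,
    remote = function(p) p$distance_km >= 50
  )
}
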