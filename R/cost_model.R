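# Per-patient cost model.
#
# Total cost over the follow-up window =
#   consultation fees
# + nurse accompaniment fee (weighted by the probability a TC used a
#   telehealth station)
# + transport on the cumulative round-trip distance of physical visits,
#   split into a medically-transported share (mode-weighted conventional
#   tariffs) and a personal-vehicle share (official cost per km)
# + amortised telehealth equipment, spread over the observed number of TC
#   patients (TC patients only).

#' Tariff parameters of one medical transport mode
#'
#' Conventional medical transport tariffs are modelled as an affine function
#' of distance with a minimum charge: `max(minimum, base_fare + per_km * d)`.
#'
#' @param base_fare euros per trip.
#' @param per_km euros per km.
#' @param minimum minimum charge in euros.
#' @return a named list.
#' @export
tariff <- function(base_fare, per_km, minimum = 0) {
  assert_pos(c(base_fare, per_km, minimum), "tariff parameters")
  list(base_fare = base_fare, per_km = per_km, minimum = minimum)
}

#' Cost inputs of the economic evaluation
#'
#' Defaults are the base-case values of the evaluation: 2020 euros, a
#' 7-month observation window, 532 TC patients, 12 telehealth stations of
#' which half are full (device-bearing) stations, and 5-year (60-month)
#' equipment amortisation. The three medical transport modes (light health
#' vehicle, taxi, ambulance) use configurable affine-with-minimum tariffs;
#' the default mode shares and tariff parameters are documented placeholders
#' approximating French conventional tariffs.
#'
#' @param consult_fee euros per (tele)consultation.
#' @param nurse_fee euros per telehealth-station TC (nurse accompaniment).
#' @param p_tc_station probability that a TC used a telehealth station.
#' @param share_med_transport share of patients medically transported.
#' @param mode_probs probabilities of (vsl, taxi, ambulance) given medical
#'   transport; must sum to 1.
#' @param nonmed_rate euros per km for personal-vehicle transport.
#' @param tariff_params named list of [tariff()]s for `vsl`, `taxi`, `amb`.
#' @param station_full_price,station_wallet_price purchase price in euros of
#'   a full station and of the device-free "wallet" variant.
#' @param installation installation cost per full station.
#' @param training_per_team training cost per team of medical professionals.
#' @param teams_per_station teams trained per station.
#' @param maintenance_monthly monthly maintenance per station.
#' @param consumables_annual consumable medical equipment per station-year.
#' @param med_equipment_per_station one-off medical equipment per full
#'   station (the wallet variant carries no connected devices).
#' @param n_stations number of telehealth stations.
#' @param share_full_stations share of stations that are full stations.
#' @param amortization_months amortisation period of the depreciable
#'   equipment (purchase, installation, training).
#' @param n_months_window observation window in months.
#' @param n_tc_patients_total observed number of TC patients over which
#'   equipment cost is spread.
#' @param n_doctors number of doctors using the videoconferencing solution.
#' @param software_monthly_per_user monthly software cost per user.
#' @param headphone_per_user one-off camera+headphone cost per user.
#' @return an object of class `cost_inputs`.
#' @export
cost_inputs <- function(consult_fee = 35.83,
                        nurse_fee = 12,
                        p_tc_station = 0.2656,
                        share_med_transport = 0.36,
                        mode_probs = c(vsl = 0.45, taxi = 0.40, amb = 0.15),
                        nonmed_rate = 0.523,
                        tariff_params = list(
                          vsl = tariff(13.75, 0.93, 13.75),
                          taxi = tariff(7.30, 1.62, 7.30),
                          amb = tariff(51.30, 2.23, 51.30)
                        ),
                        station_full_price = 21686.4,
                        station_wallet_price = 10200,
                        installation = 1680,
                        training_per_team = 1020,
                        teams_per_station = 1,
                        maintenance_monthly = 90,
                        consumables_annual = 360,
                        med_equipment_per_station = 360,
                        n_stations = 12,
                        share_full_stations = 0.5,
                        amortization_months = 60,
                        n_months_window = 7,
                        n_tc_patients_total = 532,
                        n_doctors = 30,
                        software_monthly_per_user = 70,
                        headphone_per_user = 110) {
  assert_pos(c(consult_fee, nurse_fee, nonmed_rate, station_full_price,
               station_wallet_price, installation, training_per_team,
               teams_per_station, maintenance_monthly, consumables_annual,
               med_equipment_per_station, n_stations, n_months_window,
               n_doctors, software_monthly_per_user, headphone_per_user),
             "cost inputs (prices and counts)")
  assert_prob(p_tc_station, "p_tc_station")
  assert_prob(share_med_transport, "share_med_transport")
  assert_prob(share_full_stations, "share_full_stations")
  assert_freq(mode_probs, "mode_probs")
  assert_pos(amortization_months, "amortization_months", strict = TRUE)
  if (n_tc_patients_total < 1) {
    stop("'n_tc_patients_total' must be >= 1", call. = FALSE)
  }
  if (!all(c("vsl", "taxi", "amb") %in% names(tariff_params))) {
    stop("'tariff_params' must name modes vsl, taxi, amb", call. = FALSE)
  }
  structure(list(
    consult_fee = consult_fee, nurse_fee = nurse_fee,
    p_tc_station = p_tc_station,
    share_med_transport = share_med_transport,
    mode_probs = mode_probs, nonmed_rate = nonmed_rate,
    tariff_params = tariff_params,
    station_full_price = station_full_price,
    station_wallet_price = station_wallet_price,
    installation = installation, training_per_team = training_per_team,
    teams_per_station = teams_per_station,
    maintenance_monthly = maintenance_monthly,
    consumables_annual = consumables_annual,
    med_equipment_per_station = med_equipment_per_station,
    n_stations = n_stations, share_full_stations = share_full_stations,
    amortization_months = amortization_months,
    n_months_window = n_months_window,
    n_tc_patients_total = n_tc_patients_total,
    n_doctors = n_doctors,
    software_monthly_per_user = software_monthly_per_user,
    headphone_per_user = headphone_per_user
  ), class = "cost_inputs")
}

#' @export
print.cost_inputs <- function(x, ...) {
  cat("Cost inputs (euros)\n")
  cat(sprintf("  consultation fee %.2f, nurse fee %.2f (p station %.4f)\n",
              x$consult_fee, x$nurse_fee, x$p_tc_station))
  cat(sprintf("  %d stations (%.0f%% full), amortised over %d months; window %d months, %d TC patients\n",
              x$n_stations, 100 * x$share_full_stations,
              x$amortization_months, x$n_months_window,
              x$n_tc_patients_total))
  invisible(x)
}

#' Non-medical (personal vehicle) transport cost
#'
#' @param distance_km travelled distance in km (vectorised).
#' @param inputs a [cost_inputs()] object.
#' @return euros: `nonmed_rate * distance_km`.
#' @export
nonmedical_transport_cost <- function(distance_km, inputs = cost_inputs()) {
  if (any(distance_km < 0)) stop("distance must be >= 0", call. = FALSE)
  inputs$nonmed_rate * distance_km
}

#' Medical transport cost
#'
#' Mode-probability-weighted conventional tariffs, each an affine function
#' of distance with a minimum charge.
#'
#' @inheritParams nonmedical_transport_cost
#' @return euros (vectorised over `distance_km`).
#' @export
medical_transport_cost <- function(distance_km, inputs = cost_inputs()) {
  if (any(distance_km < 0)) stop("distance must be >= 0", call. = FALSE)
  assert_freq(inputs$mode_probs, "mode_probs")
  out <- 0
  for (mode in c("vsl", "taxi", "amb")) {
    tp <- inputs$tariff_params[[mode]]
    out <- out + inputs$mode_probs[[mode]] *
      pmax(tp$minimum, tp$base_fare + tp$per_km * distance_km)
  }
  out
}

#' Monthly equipment cost of a full and a wallet telehealth station
#'
#' The depreciable part (purchase + installation + training for a full
#' station; purchase + training for a wallet) is spread over
#' `amortization_months`; consumables accrue at 1/12 of their annual rate.
#'
#' @param inputs a [cost_inputs()] object.
#' @return named list with `device`, `wallet` (euros per month) and their
#'   `device_depreciable`/`wallet_depreciable` parts.
#' @export
monthly_equipment_costs <- function(inputs = cost_inputs()) {
  dep_full <- (inputs$station_full_price + inputs$installation +
                 inputs$training_per_team * inputs$teams_per_station) /
    inputs$amortization_months
  dep_wallet <- (inputs$station_wallet_price +
                   inputs$training_per_team * inputs$teams_per_station) /
    inputs$amortization_months
  cons <- inputs$consumables_annual / 12
  list(device = dep_full + cons, wallet = dep_wallet + cons,
       device_depreciable = dep_full, wallet_depreciable = dep_wallet)
}

#' Telehealth equipment cost per TC patient
#'
#' Station fleet costs (amortised purchase/installation/training,
#' consumables, maintenance) over the observation window, one-off medical
#' equipment for the full (device-bearing) stations, the videoconferencing
#' software over the window and one-off camera/headphone for each doctor,
#' all spread over the observed number of TC patients.
#'
#' @param inputs a [cost_inputs()] object.
#' @return euros per TC patient.
#' @export
equipment_cost_per_tc_patient <- function(inputs = cost_inputs()) {
  if (inputs$n_tc_patients_total <= 0) {
    stop("'n_tc_patients_total' must be positive", call. = FALSE)
  }
  n_full <- round(inputs$n_stations * inputs$share_full_stations)
  n_wallet <- inputs$n_stations - n_full
  m <- monthly_equipment_costs(inputs)
  fleet_monthly <- n_full * m$device + n_wallet * m$wallet +
    inputs$n_stations * inputs$maintenance_monthly
  total <- fleet_monthly * inputs$n_months_window +
    n_full * inputs$med_equipment_per_station +
    inputs$n_doctors * inputs$software_monthly_per_user * inputs$n_months_window +
    inputs$n_doctors * inputs$headphone_per_user
  total / inputs$n_tc_patients_total
}

#' Per-patient total cost and its decomposition
#'
#' @param pop a `patient_population` data.frame (or any data.frame with the
#'   columns `n_consult`, `n_tc`, `distance_km`, `group`).
#' @param inputs a [cost_inputs()] object.
#' @return a `data.frame` with one row per patient: `patient_id`, `group`,
#'   `consult_cost`, `nurse_fee_cost`, `medical_transport`,
#'   `nonmedical_transport`, `equipment` and `total` (euros). The total is
#'   the exact sum of the five components; the equipment component is zero
#'   for CS patients. Travel counts two one-way distances per physical
#'   (non-TC) visit; teleconsultations generate no travel.
#' @export
patient_total_cost <- function(pop, inputs = cost_inputs()) {
  stopifnot(is.data.frame(pop))
  needed <- c("n_consult", "n_tc", "distance_km", "group")
  missing_cols <- setdiff(needed, names(pop))
  if (length(missing_cols)) {
    stop("population table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(pop$n_tc > pop$n_consult)) {
    stop("invalid record: n_tc exceeds n_consult", call. = FALSE)
  }
  n_physical <- pop$n_consult - pop$n_tc
  dist <- 2 * pop$distance_km * n_physical
  consult_cost <- pop$n_consult * inputs$consult_fee
  nurse_fee_cost <- inputs$p_tc_station * pop$n_tc * inputs$nurse_fee
  med <- ifelse(dist > 0,
                inputs$share_med_transport * medical_transport_cost(dist, inputs),
                0)
  nonmed <- (1 - inputs$share_med_transport) *
    nonmedical_transport_cost(dist, inputs)
  equip <- ifelse(pop$group == "TC", equipment_cost_per_tc_patient(inputs), 0)
  out <- data.frame(
    patient_id = pop$patient_id %||% seq_len(nrow(pop)),
    group = pop$group,
    consult_cost = consult_cost,
    nurse_fee_cost = nurse_fee_cost,
    medical_transport = med,
    nonmedical_transport = nonmed,
    equipment = equip,
    stringsAsFactors = FALSE
  )
  out$total <- out$consult_cost + out$nurse_fee_cost + out$medical_transport +
    out$nonmedical_transport + out$equipment
  out
}
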