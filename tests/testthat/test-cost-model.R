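test_that("transport costs follow the tariff arithmetic", {
  ci <- cost_inputs()
  expect_identical(nonmedical_transport_cost(0, ci), 0)
  expect_equal(nonmedical_transport_cost(10, ci), 5.23)
  expect_equal(nonmedical_transport_cost(100, ci), 52.30)
  expect_error(nonmedical_transport_cost(-1, ci), "distance")

  # single mode, affine branch: 2 + 1 * 10 = 12
  ci1 <- cost_inputs(mode_probs = c(vsl = 1, taxi = 0, amb = 0),
                     tariff_params = list(vsl = tariff(2, 1, 0),
                                          taxi = tariff(0, 0, 0),
                                          amb = tariff(0, 0, 0)))
  expect_equal(medical_transport_cost(10, ci1), 12)

  # equal constant tariffs: any mode mix returns the constant
  cic <- cost_inputs(mode_probs = c(vsl = 0.2, taxi = 0.5, amb = 0.3),
                     tariff_params = list(vsl = tariff(7, 0, 0),
                                          taxi = tariff(7, 0, 0),
                                          amb = tariff(7, 0, 0)))
  expect_equal(medical_transport_cost(123, cic), 7)

  # below every minimum-charge break-even: probability-weighted minimums
  cim <- cost_inputs(mode_probs = c(vsl = 0.5, taxi = 0.3, amb = 0.2),
                     tariff_params = list(vsl = tariff(1, 0.1, 20),
                                          taxi = tariff(1, 0.1, 30),
                                          amb = tariff(1, 0.1, 40)))
  expect_equal(medical_transport_cost(5, cim), 0.5 * 20 + 0.3 * 30 + 0.2 * 40)
})

test_that("equipment cost per TC patient has the documented composition", {
  expect_equal(equipment_cost_per_tc_patient(cost_inputs(
    station_full_price = 0, station_wallet_price = 0, installation = 0,
    training_per_team = 0, maintenance_monthly = 0, consumables_annual = 0,
    med_equipment_per_station = 0, software_monthly_per_user = 0,
    headphone_per_user = 0)), 0)

  base <- equipment_cost_per_tc_patient(cost_inputs())
  # removing the software subscription removes exactly 70 * 30 * 7 / 532
  no_soft <- equipment_cost_per_tc_patient(
    cost_inputs(software_monthly_per_user = 0))
  expect_equal(base - no_soft, 70 * 30 * 7 / 532, tolerance = 1e-12)
  expect_error(
    equipment_cost_per_tc_patient(cost_inputs(n_tc_patients_total = 0)),
    "n_tc_patients_total")
})

test_that("amortization acts linearly on the depreciable part only", {
  m60 <- monthly_equipment_costs(cost_inputs(amortization_months = 60))
  m120 <- monthly_equipment_costs(cost_inputs(amortization_months = 120))
  expect_equal(m120$device_depreciable, m60$device_depreciable / 2)
  expect_equal(m120$wallet_depreciable, m60$wallet_depreciable / 2)
  # consumables (the non-depreciable part of the monthly cost) unchanged
  expect_equal(m60$device - m60$device_depreciable,
               m120$device - m120$device_depreciable)
  # software and one-off items unchanged: the full cost difference is
  # exactly the halved depreciable fleet charge over the window
  e60 <- equipment_cost_per_tc_patient(cost_inputs())
  e120 <- equipment_cost_per_tc_patient(cost_inputs(amortization_months = 120))
  dep_fleet <- (6 * m60$device_depreciable + 6 * m60$wallet_depreciable)
  expect_equal(e60 - e120, dep_fleet / 2 * 7 / 532, tolerance = 1e-12)
})

test_that("per-patient totals decompose exactly and respect group rules", {
  pop <- test_population()
  costs <- patient_total_cost(pop)
  comp <- costs$consult_cost + costs$nurse_fee_cost +
    costs$medical_transport + costs$nonmedical_transport + costs$equipment
  expect_lt(max(abs(costs$total - comp)), 1e-9)
  expect_true(all(costs[, 3:7] >= 0))
  expect_true(all(costs$equipment[costs$group == "CS"] == 0))
  expect_true(all(costs$equipment[costs$group == "TC"] > 0))

  # one CS consultation at zero distance costs the fee alone
  rec <- data.frame(patient_id = 1L, n_consult = 1L, n_tc = 0L,
                    distance_km = 0, group = "CS")
  expect_equal(patient_total_cost(rec)$total, 35.83)

  # a TC patient with no physical visit generates no transport cost
  rec2 <- data.frame(patient_id = 1L, n_consult = 2L, n_tc = 2L,
                     distance_km = 40, group = "TC")
  c2 <- patient_total_cost(rec2)
  expect_equal(c2$medical_transport, 0)
  expect_equal(c2$nonmedical_transport, 0)

  # group mean consultation-fee cost tracks the mean consultation count
  cs_mean <- mean(costs$consult_cost[pop$group == "CS"])
  expect_equal(cs_mean, mean(pop$n_consult[pop$group == "CS"]) * 35.83)
})

test_that("total cost is monotone in distance, consultations and prices", {
  rec <- function(d, n) data.frame(patient_id = 1L, n_consult = n,
                                   n_tc = 0L, distance_km = d, group = "CS")
  t_base <- patient_total_cost(rec(10, 2))$total
  expect_gte(patient_total_cost(rec(20, 2))$total, t_base)
  expect_gte(patient_total_cost(rec(10, 3))$total, t_base)
  up <- cost_inputs(consult_fee = 50, nonmed_rate = 1)
  expect_gte(patient_total_cost(rec(10, 2), up)$total, t_base)
})

test_that("invalid cost inputs are rejected", {
  expect_error(cost_inputs(mode_probs = c(vsl = 0.5, taxi = 0.5, amb = 0.1)),
               "mode_probs")
  expect_error(cost_inputs(maintenance_monthly = -1), "prices")
  expect_error(cost_inputs(p_tc_station = 1.5), "p_tc_station")
})
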