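# teleconsult

Economic and organisational evaluation of hospital **teleconsultations
(TC)** against in-person specialist consultations (**CS**), for health
economists and hospital planners deciding whether — and how intensively — to
deploy a videoconferencing solution and a fleet of telehealth stations.

The package combines two evaluation arms around one per-patient cost model:

1. **Matched cost comparison.** The total cost of patient *i* over a
   298-day follow-up window is

   ```
   total_i = NbConsult_i * fee
           + p_station * NbTC_i * nurse_fee
           + p_medTravel * MED(dist_i) + (1 - p_medTravel) * rate_km * dist_i
           + 1{TC patient} * Equipment / N_TC
   ```

   where `dist_i` is the cumulative round-trip distance of physical visits,
   `MED()` is the probability-weighted mix of the three French medical
   transport tariffs (light health vehicle, taxi, ambulance; each affine in
   distance with a minimum charge), and `Equipment` spreads the amortised
   telehealth station fleet, software, training and one-off hardware over
   the observed number of TC patients. Because selection into the TC group
   is covariate-driven, the comparison runs through a propensity-score
   logit, greedy 1:1 nearest-neighbour matching, balance diagnostics,
   a non-parametric bootstrap interval for the incremental cost, and a
   tornado one-at-a-time sensitivity analysis.

2. **Discrete-event simulation.** Arrivals are daily Poisson draws resampled
   from a patient population; each agent takes one of three pathways
   (CS / video TC / telehealth-station TC) with configured probabilities,
   subject to an eligibility rule, a video cap for patients over 80, nurse
   sick-leave and a 7-TC-per-station daily quota (redirects count as
   transfers to CS). KPIs per replication: total cost, average cost per
   consultation type, doctor/admin/nurse minutes, transfers, completed
   volumes, travel time and travel time avoided. Scenario sweeps over the
   probability simplex feed average-cost-versus-volume curves and
   break-even amortisation levels per population stratum.

A synthetic-population generator (covariate marginals, selection
coefficients, per-group consultation-count distributions, heavy-tailed
distances) makes every stage testable end-to-end without the private
clinical data the calibration derives from.

## Worked example

```r
library(teleconsult)

pop  <- generate_population(population_params(n_patients = 20000, seed = 7))
fit  <- fit_propensity(pop)
m    <- match_1to1(pop, fit$scores)
m
#> Matched sample: 634 pairs (0 TC unmatched)
#>   propensity-score SMD: 0.991 before, 0.000 after
#>   max |covariate SMD| after matching: 0.080

costs <- patient_total_cost(pop, cost_inputs())
inc   <- add_bootstrap_ci(incremental_cost(m, costs), B = 1000, seed = 1)
inc
#> Incremental cost: 116.44 = 332.14 (TC) - 215.70 (CS), 634 pairs
#>   1000-replicate bootstrap 95% CI: (98.20, 136.87)
```

The matched sample removes the covariate imbalance the generator planted
(all standardized mean differences fall below 0.1), and the incremental
cost isolates what TC patients cost on top of comparable CS patients: on
this synthetic cohort, more consultations per patient plus the equipment
charge (about €104 per TC patient at the default inputs) outweigh the
transport savings.

On the simulation side:

```r
r <- run_replication(scenario_config(), seed = 11, population = pop)
r
#> KPI report: 113969 arrivals, volumes CS/video/station = 109269/3704/1249, 328 transfers
#>   total cost 9215426 EUR; doctor/admin/nurse minutes 2464400/181750/18696

break_even(fixed_cost_totals()$video, reference_cs_cost = 60.91,
           variable_cost = 35.83)
#> Break-even: 5,156 TCs (4.1/day; 0.3/station/day)
```

`stratified_break_even()` repeats the break-even computation per distance
stratum (urban / peri-urban / remote) and shows the rates falling with
distance, and `run_experiment(experiment_plan("exp1", grid_step = 0.1))`
sweeps all 66 pathway-probability combinations.

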