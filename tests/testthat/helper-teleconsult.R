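# Shared fixtures, built in code at test time.

# small synthetic cohort with the default (cohort-calibrated) selection
test_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_population(population_params(n_patients = 4000,
                                                      seed = 11L))
    }
    cache
  }
})

# a matched sample constructed directly from ids (for desk arithmetic)
fake_matched <- function(tc_ids, cs_ids) {
  structure(list(pairs = data.frame(tc_id = tc_ids, cs_id = cs_ids)),
            class = "matched_sample")
}

# cost table with prescribed totals
fake_costs <- function(ids, totals, group = NULL) {
  data.frame(patient_id = ids, total = totals,
             group = group %||% rep("CS", length(ids)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten a KPI report for comparisons
kpi_vector_public <- function(r) teleconsult:::kpi_vector(r)

# larger cohort for end-to-end balance checks
test_population_large <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_population(population_params(n_patients = 20000,
                                                      seed = 7L))
    }
    cache
  }
})

# short-horizon scenario for unit tests
small_scenario <- function(...) {
  args <- utils::modifyList(list(horizon_days = 60, arrival_rate = 25,
                                 replications = 3), list(...))
  do.call(scenario_config, args)
}
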