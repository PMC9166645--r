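test_that("generation is deterministic given the seed and hits its targets", {
  p <- population_params(n_patients = 4000, seed = 3L)
  a <- generate_population(p)
  b <- generate_population(p)
  expect_identical(a, b)

  pop <- test_population()
  # empirical TC fraction within 3 SE of the target
  tgt <- 424 / 13626
  se <- sqrt(tgt * (1 - tgt) / nrow(pop))
  expect_lt(abs(mean(pop$group == "TC") - tgt), 3 * se)
  # group = TC iff at least one teleconsultation flag
  flags_n <- vapply(strsplit(pop$tc_flags, ";"),
                    function(f) sum(as.integer(f)), integer(1))
  expect_identical(pop$group == "TC", flags_n > 0L)
  expect_identical(flags_n, pop$n_tc)
  # consult dates inside the follow-up window, at least one consultation
  dates <- unlist(strsplit(pop$consult_dates, ";"))
  expect_true(all(as.integer(dates) >= 0 & as.integer(dates) <= 298))
  expect_true(all(pop$n_consult >= 1L))
  expect_true(all(pop$n_tc <= pop$n_consult))
  # deterministic distance -> time link
  expect_equal(pop$travel_time_min, round(pop$distance_km / 0.9, 2),
               tolerance = 1e-8)
})

test_that("group-wise consultation-count means match their configured targets", {
  pop <- generate_population(population_params(n_patients = 1e5, seed = 21L))
  m_tc <- mean(pop$n_consult[pop$group == "TC"])
  m_cs <- mean(pop$n_consult[pop$group == "CS"])
  expect_lt(abs(m_tc - 3.53), 0.05)
  expect_lt(abs(m_cs - 2.94), 0.05)
})

test_that("selection coefficients control covariate imbalance", {
  # zero selection: no covariate imbalance beyond noise
  null_coefs <- list(gender = c(female = 0, male = 0), age = 0)
  pop0 <- generate_population(population_params(
    n_patients = 10000, seed = 5L, selection_coefficients = null_coefs))
  bal0 <- balance_table(pop0)
  expect_lt(max(abs(bal0$smd)), 0.15)
  # default (cohort-calibrated) selection: detectable imbalance
  bal1 <- balance_table(test_population())
  expect_gt(max(abs(bal1$smd)), 0.1)
})

test_that("distance distribution populates all three geographic strata", {
  pop <- test_population()
  expect_gt(mean(pop$distance_km < 20), 0)
  expect_gt(mean(pop$distance_km >= 20 & pop$distance_km < 50), 0)
  expect_gt(mean(pop$distance_km >= 50), 0)
  # mean one-way travel time close to the cohort's ~24 minutes
  expect_lt(abs(mean(pop$travel_time_min) - 24), 3)
})

test_that("agent streams are Poisson, filterable and reproducible", {
  pop <- test_population()
  ag <- sample_agents(NULL, n_days = 1265, arrival_rate = 89.953782,
                      seed = 7L, population = pop)
  daily <- tabulate(ag$day, nbins = 1265)
  se <- sqrt(89.953782 / 1265)
  expect_lt(abs(mean(daily) - 89.953782), 3 * se)

  old <- sample_agents(NULL, n_days = 200, arrival_rate = 20.64, seed = 8L,
                       population = pop, filter = function(p) p$age > 80)
  expect_true(all(old$age > 80))
  se2 <- sqrt(20.64 / 200)
  expect_lt(abs(mean(tabulate(old$day, 200)) - 20.64), 3 * se2)

  s1 <- sample_agents(NULL, 1, 5, seed = 9L, population = pop)
  s2 <- sample_agents(NULL, 1, 5, seed = 9L, population = pop)
  expect_identical(s1, s2)
  expect_error(sample_agents(NULL, 0, 5, population = pop), "n_days")
})

test_that("population tables round-trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  pop <- test_population()[1:50, ]
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(as.data.frame(back), as.data.frame(pop),
               ignore_attr = TRUE)

  # empty collection -> header-only file -> empty collection
  write_population(pop[0, ], path)
  expect_identical(nrow(read_population(path)), 0L)

  # corrupted row is reported with its line number
  write_population(pop, path)
  lines <- readLines(path)
  lines[11] <- sub("^\\d+", "not_a_number", lines[11])
  writeLines(lines, path)
  expect_error(read_population(path), "line\\(s\\): 11")
})

test_that("invalid generator configurations name the offending field", {
  expect_error(population_params(n_patients = 0), "n_patients")
  expect_error(population_params(tc_fraction_target = 1.2),
               "tc_fraction_target")
  bad <- list(gender = c(female = 0.7, male = 0.7),
              icd10_chapter = c(a = 1), care_unit = c(a = 1),
              pathway_type = c(a = 1))
  expect_error(population_params(covariate_marginals = bad), "gender")
})
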