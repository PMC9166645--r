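# Synthetic patient population generator.
#
# Emulates the statistical structure the downstream analyses assume: a large
# cohort of outpatients of whom a small fraction used teleconsultations (TC),
# with covariate-driven selection into the TC group, higher consultation
# counts for TC patients, and a heavy-tailed travel-distance distribution.

# ---- calibration defaults --------------------------------------------------
# Category frequencies of the control (CS) group and the TC group in the
# source cohort; CS frequencies are the generation marginals, the TC/CS log
# odds drive the default selection coefficients.

icd10_table <- function() {
  data.frame(
    category = c("infectious", "neoplasms", "blood", "endocrine", "mental",
                 "nervous", "eye", "circulatory", "respiratory", "digestive",
                 "skin", "musculoskeletal", "genitourinary", "pregnancy",
                 "congenital", "symptoms", "injury", "factors"),
    cs = c(0.39, 12.72, 0.11, 1.93, 0.01, 1.79, 5.86, 7.60, 0.50, 20.27,
           1.19, 19.12, 8.38, 0.01, 0.12, 3.12, 2.17, 14.73) / 100,
    tc = c(0, 23.58, 0, 3.54, 0, 0.24, 0, 21.70, 0, 17.92,
           0.24, 10.61, 12.97, 0, 0.47, 2.36, 0.24, 6.13) / 100,
    stringsAsFactors = FALSE
  )
}

care_unit_table <- function() {
  data.frame(
    category = c("ambulatory_emergency", "ambulatory", "short_stay",
                 "anesthesia", "other", "digestive_surgery", "sleep",
                 "gastroenterology", "gynecology", "medicine", "neurology",
                 "ophthalmology", "orthopedics", "radiology", "resuscitation",
                 "monitoring", "urology", "vascular"),
    cs = c(2.57, 25.96, 18.16, 0.01, 0.00, 11.66, 7.38, 0.83, 4.29, 0.27,
           0.89, 0.17, 13.19, 0.01, 1.46, 2.91, 5.39, 4.87) / 100,
    tc = c(0, 33.73, 12.97, 0.24, 0.24, 13.21, 0.47, 0.24, 5.42, 0.94,
           1.65, 0, 4.48, 0, 0.24, 0.24, 15.57, 10.38) / 100,
    stringsAsFactors = FALSE
  )
}

pathway_table <- function() {
  data.frame(category = c("after", "before", "both"),
             cs = c(25.47, 38.46, 36.06) / 100,
             tc = c(20.99, 29.95, 49.06) / 100,
             stringsAsFactors = FALSE)
}

gender_table <- function() {
  data.frame(category = c("female", "male"),
             cs = c(53.92, 46.08) / 100,
             tc = c(50.94, 49.06) / 100,
             stringsAsFactors = FALSE)
}

# Log odds of TC vs CS membership per category; categories never observed
# in the TC group get a strongly negative coefficient (effectively excluded).
log_odds_coefs <- function(tab, floor = -6) {
  lo <- ifelse(tab$tc <= 0 | tab$cs <= 0, floor, log(tab$tc / tab$cs))
  stats::setNames(lo, tab$category)
}

normalize_freq <- function(tab) {
  stats::setNames(tab$cs / sum(tab$cs), tab$category)
}

#' Parameters of the synthetic population generator
#'
#' Defaults are calibrated to the source cohort: n = 13,626 patients of whom
#' about 3.1% are TC patients, category marginals taken from the control
#' group, selection coefficients equal to the observed per-category TC/CS
#' log odds, per-group zero-truncated-Poisson consultation counts with means
#' 3.53 (TC) and 2.94 (CS), a lognormal one-way distance with median 15 km
#' and log-sd 0.85 (so that mean travel time is about 24 minutes at
#' 0.9 km/min), and a 298-day follow-up window (165 days before + 133 after
#' the index hospital stay).
#'
#' @param n_patients number of patients to generate.
#' @param tc_fraction_target expected fraction of TC patients; the selection
#'   intercept is solved numerically so the generated fraction matches it in
#'   expectation whatever the covariate coefficients.
#' @param covariate_marginals named list of frequency vectors for `gender`,
#'   `icd10_chapter`, `care_unit` and `pathway_type`; each must sum to 1.
#' @param age_distribution `c(mean, sd)` in years (truncated to 18..100).
#' @param distance_distribution `c(meanlog, sdlog)` of the lognormal one-way
#'   road distance in km.
#' @param travel_speed km per minute converting distance to one-way travel
#'   time.
#' @param living_std_distribution `c(mean, sd)` of municipal median standard
#'   of living in euros.
#' @param density_distribution `c(meanlog, sdlog)` of municipal population
#'   density (same scale as the cohort tables, around 10).
#' @param selection_coefficients named list of per-category logit
#'   coefficients (`gender`, `icd10_chapter`, `care_unit`, `pathway_type`)
#'   plus optional `age`, `travel_time` slopes, linking covariates to TC
#'   membership. All-zero coefficients give two exchangeable groups.
#' @param consult_count_params list with `mean_tc`, `mean_cs` (target means
#'   of the zero-truncated Poisson counts) and `p_extra_tc` (probability
#'   that each consultation beyond the first of a TC patient is itself a
#'   teleconsultation).
#' @param followup_days follow-up window length in days.
#' @param seed RNG seed.
#' @return an object of class `population_params`.
#' @export
population_params <- function(n_patients = 13626,
                              tc_fraction_target = 424 / 13626,
                              covariate_marginals = list(
                                gender = normalize_freq(gender_table()),
                                icd10_chapter = normalize_freq(icd10_table()),
                                care_unit = normalize_freq(care_unit_table()),
                                pathway_type = normalize_freq(pathway_table())
                              ),
                              age_distribution = c(mean = 61.5, sd = 16),
                              distance_distribution = c(meanlog = log(15),
                                                        sdlog = 0.85),
                              travel_speed = 0.9,
                              living_std_distribution = c(mean = 19873,
                                                          sd = 3000),
                              density_distribution = c(meanlog = 2.0,
                                                       sdlog = 0.7),
                              selection_coefficients = list(
                                gender = log_odds_coefs(gender_table()),
                                icd10_chapter = log_odds_coefs(icd10_table()),
                                care_unit = log_odds_coefs(care_unit_table()),
                                pathway_type = log_odds_coefs(pathway_table()),
                                age = 0, travel_time = 0
                              ),
                              consult_count_params = list(mean_tc = 3.53,
                                                          mean_cs = 2.94,
                                                          p_extra_tc = 0.07),
                              followup_days = 298,
                              seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("configuration error in 'n_patients': must be a positive count",
         call. = FALSE)
  }
  if (tc_fraction_target <= 0 || tc_fraction_target >= 1) {
    stop("configuration error in 'tc_fraction_target': must be in (0, 1)",
         call. = FALSE)
  }
  for (nm in c("gender", "icd10_chapter", "care_unit", "pathway_type")) {
    f <- covariate_marginals[[nm]]
    if (is.null(f)) {
      stop(sprintf("configuration error in 'covariate_marginals$%s': missing",
                   nm), call. = FALSE)
    }
    tryCatch(assert_freq(f, nm),
             error = function(e) stop(sprintf(
               "configuration error in 'covariate_marginals$%s': %s",
               nm, conditionMessage(e)), call. = FALSE))
  }
  assert_pos(travel_speed, "travel_speed", strict = TRUE)
  assert_pos(followup_days, "followup_days", strict = TRUE)
  if (consult_count_params$mean_tc <= 1 || consult_count_params$mean_cs <= 1) {
    stop("configuration error in 'consult_count_params': zero-truncated ",
         "means must exceed 1", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    tc_fraction_target = tc_fraction_target,
    covariate_marginals = covariate_marginals,
    age_distribution = age_distribution,
    distance_distribution = distance_distribution,
    travel_speed = travel_speed,
    living_std_distribution = living_std_distribution,
    density_distribution = density_distribution,
    selection_coefficients = selection_coefficients,
    consult_count_params = consult_count_params,
    followup_days = followup_days,
    seed = as.integer(seed)
  ), class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Synthetic population parameters\n")
  cat(sprintf("  patients: %d, target TC fraction: %.4f\n",
              x$n_patients, x$tc_fraction_target))
  cat(sprintf("  consult means (TC/CS): %.2f / %.2f, follow-up: %d days\n",
              x$consult_count_params$mean_tc, x$consult_count_params$mean_cs,
              x$followup_days))
  invisible(x)
}

# lambda of a zero-truncated Poisson with the requested mean
ztp_lambda <- function(target_mean) {
  stats::uniroot(function(l) l / (1 - exp(-l)) - target_mean,
                 interval = c(1e-8, target_mean + 10), tol = 1e-12)$root
}

# exact inverse-CDF sampler for the zero-truncated Poisson
rztpois <- function(n, lambda) {
  u <- stats::runif(n, min = stats::dpois(0, lambda), max = 1)
  stats::qpois(u, lambda)
}

# linear predictor of the selection logit (without intercept)
selection_linpred <- function(pop, coefs) {
  lp <- rep(0, nrow(pop))
  for (nm in c("gender", "icd10_chapter", "care_unit", "pathway_type")) {
    v <- coefs[[nm]]
    if (!is.null(v)) {
      m <- v[pop[[nm]]]
      m[is.na(m)] <- 0
      lp <- lp + as.numeric(m)
    }
  }
  if (!is.null(coefs$age)) lp <- lp + coefs$age * (pop$age - mean(pop$age))
  if (!is.null(coefs$travel_time)) {
    lp <- lp + coefs$travel_time * (pop$travel_time_min - mean(pop$travel_time_min))
  }
  lp
}

#' Generate a synthetic patient population
#'
#' Draws covariates independently from the configured marginals, assigns TC
#' membership from a logit selection model whose intercept is solved so the
#' expected TC fraction equals `tc_fraction_target`, then draws per-group
#' consultation counts (zero-truncated Poisson), consultation dates (uniform
#' over the follow-up window) and per-consultation teleconsultation flags.
#'
#' @param params a [population_params()] object.
#' @return a `data.frame` of class `patient_population`, one row per patient,
#'   with columns `patient_id`, `age`, `gender`, `distance_km`,
#'   `travel_time_min`, `median_living_std`, `pop_density`, `icd10_chapter`,
#'   `care_unit`, `pathway_type`, `n_consult`, `n_tc`, `consult_dates`,
#'   `tc_flags` (both ";"-separated within the cell) and `group`
#'   ("TC"/"CS").
#' @export
generate_population <- function(params) {
  stopifnot(inherits(params, "population_params"))
  n <- params$n_patients
  set.seed(derive_seed(params$seed, "covariates"))

  marg <- params$covariate_marginals
  draw_cat <- function(f) sample(names(f), n, replace = TRUE, prob = f)
  age <- pmin(pmax(stats::rnorm(n, params$age_distribution[[1L]],
                                params$age_distribution[[2L]]), 18), 100)
  distance_km <- stats::rlnorm(n, params$distance_distribution[[1L]],
                               params$distance_distribution[[2L]])
  pop <- data.frame(
    patient_id = seq_len(n),
    age = round(age, 1),
    gender = draw_cat(marg$gender),
    distance_km = round(distance_km, 2),
    travel_time_min = NA_real_,
    median_living_std = round(pmax(stats::rnorm(
      n, params$living_std_distribution[[1L]],
      params$living_std_distribution[[2L]]), 8000), 0),
    pop_density = round(stats::rlnorm(n, params$density_distribution[[1L]],
                                      params$density_distribution[[2L]]), 2),
    icd10_chapter = draw_cat(marg$icd10_chapter),
    care_unit = draw_cat(marg$care_unit),
    pathway_type = draw_cat(marg$pathway_type),
    stringsAsFactors = FALSE
  )
  # deterministic link between distance and one-way travel time
  pop$travel_time_min <- round(pop$distance_km / params$travel_speed, 2)

  # selection into the TC group: solve the intercept for the target fraction
  set.seed(derive_seed(params$seed, "selection"))
  lp <- selection_linpred(pop, params$selection_coefficients)
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + lp)) - params$tc_fraction_target,
    interval = c(-30, 30), tol = 1e-10
  )$root
  is_tc <- stats::runif(n) < stats::plogis(alpha + lp)

  # consultation histories
  set.seed(derive_seed(params$seed, "consultations"))
  cc <- params$consult_count_params
  lam_tc <- ztp_lambda(cc$mean_tc)
  lam_cs <- ztp_lambda(cc$mean_cs)
  n_consult <- integer(n)
  n_consult[is_tc] <- rztpois(sum(is_tc), lam_tc)
  n_consult[!is_tc] <- rztpois(sum(!is_tc), lam_cs)
  n_tc <- integer(n)
  n_tc[is_tc] <- 1L + stats::rbinom(sum(is_tc), n_consult[is_tc] - 1L,
                                    cc$p_extra_tc)
  dates <- lapply(n_consult, function(k)
    sort(sample.int(params$followup_days + 1L, k, replace = TRUE) - 1L))
  flags <- mapply(function(k, m) {
    f <- rep(0L, k)
    if (m > 0L) f[sample.int(k, m)] <- 1L
    f
  }, n_consult, n_tc, SIMPLIFY = FALSE)

  pop$n_consult <- n_consult
  pop$n_tc <- n_tc
  pop$consult_dates <- join_ints(dates)
  pop$tc_flags <- join_ints(flags)
  pop$group <- ifelse(is_tc, "TC", "CS")
  attr(pop, "params") <- params
  class(pop) <- c("patient_population", "data.frame")
  pop
}

#' @export
print.patient_population <- function(x, ...) {
  cat(sprintf("Synthetic patient population: %d patients (%d TC, %d CS)\n",
              nrow(x), sum(x$group == "TC"), sum(x$group == "CS")))
  cat(sprintf("  mean consultations: TC %.2f, CS %.2f; mean one-way travel %.1f min\n",
              mean(x$n_consult[x$group == "TC"]),
              mean(x$n_consult[x$group == "CS"]),
              mean(x$travel_time_min)))
  invisible(x)
}

#' Sample a day-indexed agent stream for the simulation
#'
#' Daily arrival counts are independent Poisson draws; agent attributes are
#' drawn by resampling rows of a generated (or supplied) population with
#' replacement, optionally after filtering.
#'
#' @param params a [population_params()] object (ignored if `population` is
#'   supplied).
#' @param n_days number of simulated days.
#' @param arrival_rate mean arrivals per day.
#' @param seed RNG seed for the stream.
#' @param population optional `patient_population` to resample from.
#' @param filter optional predicate taking the population data.frame and
#'   returning a logical row mask (e.g. `function(p) p$age > 80`).
#' @return a `data.frame` with a `day` column (1..n_days) plus the resampled
#'   patient attribute columns.
#' @export
sample_agents <- function(params, n_days, arrival_rate, seed = 1L,
                          population = NULL, filter = NULL) {
  if (!is.numeric(n_days) || n_days <= 0) {
    stop("'n_days' must be positive", call. = FALSE)
  }
  assert_pos(arrival_rate, "arrival_rate", strict = TRUE)
  if (is.null(population)) population <- generate_population(params)
  if (!is.null(filter)) {
    keep <- filter(population)
    if (!any(keep)) stop("population filter left no agents", call. = FALSE)
    population <- population[keep, , drop = FALSE]
  }
  set.seed(derive_seed(seed, "arrivals"))
  counts <- stats::rpois(n_days, arrival_rate)
  total <- sum(counts)
  set.seed(derive_seed(seed, "agent_attributes"))
  idx <- sample.int(nrow(population), total, replace = TRUE)
  out <- population[idx, , drop = FALSE]
  out$day <- rep(seq_len(n_days), counts)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out[, c("day", setdiff(names(out), "day"))]
}

population_columns <- c(
  "patient_id", "age", "gender", "distance_km", "travel_time_min",
  "median_living_std", "pop_density", "icd10_chapter", "care_unit",
  "pathway_type", "n_consult", "n_tc", "consult_dates", "tc_flags", "group"
)

#' Write / read a patient population table
#'
#' Tab-delimited UTF-8 text with a header and "." decimal separator;
#' `consult_dates` and `tc_flags` are ";"-separated within their cells.
#' `read_population(write_population(x))` returns `x` field-for-field.
#'
#' @param pop a `patient_population` data.frame.
#' @param path file path.
#' @return `write_population` returns `path` invisibly; `read_population`
#'   returns a validated `patient_population`.
#' @export
write_population <- function(pop, path) {
  stopifnot(is.data.frame(pop))
  utils::write.table(as.data.frame(pop)[, population_columns, drop = FALSE],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(population_columns, names(raw))
  if (length(missing_cols)) {
    stop("malformed population file: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  int <- function(col) suppressWarnings(as.integer(raw[[col]]))
  pop <- data.frame(
    patient_id = int("patient_id"), age = num("age"),
    gender = raw$gender, distance_km = num("distance_km"),
    travel_time_min = num("travel_time_min"),
    median_living_std = num("median_living_std"),
    pop_density = num("pop_density"), icd10_chapter = raw$icd10_chapter,
    care_unit = raw$care_unit, pathway_type = raw$pathway_type,
    n_consult = int("n_consult"), n_tc = int("n_tc"),
    consult_dates = raw$consult_dates, tc_flags = raw$tc_flags,
    group = raw$group, stringsAsFactors = FALSE
  )
  dates <- split_ints(pop$consult_dates)
  flags <- split_ints(pop$tc_flags)
  bad <- is.na(pop$patient_id) | is.na(pop$age) | is.na(pop$distance_km) |
    is.na(pop$n_consult) | is.na(pop$n_tc) |
    vapply(dates, anyNA, logical(1)) | vapply(flags, anyNA, logical(1)) |
    lengths(dates) != pop$n_consult |
    vapply(flags, function(f) sum(f), integer(1)) != pop$n_tc |
    pop$n_consult < 1L | pop$n_tc > pop$n_consult |
    !(pop$group %in% c("TC", "CS")) |
    (pop$group == "TC") != (pop$n_tc > 0L)
  if (any(bad)) {
    # +1 for the header: report physical line numbers in the file
    stop("malformed population rows at line(s): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
  class(pop) <- c("patient_population", "data.frame")
  pop
}
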