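# Incremental cost on the matched sample: point estimate, non-parametric
# bootstrap percentile interval, and one-at-a-time (tornado) deterministic
# sensitivity analysis.

# extract matched total-cost vectors per group
matched_costs <- function(matched, costs) {
  stopifnot(inherits(matched, "matched_sample"), is.data.frame(costs))
  lookup <- stats::setNames(costs$total, costs$patient_id)
  tc <- lookup[as.character(matched$pairs$tc_id)]
  cs <- lookup[as.character(matched$pairs$cs_id)]
  if (anyNA(tc) || anyNA(cs)) {
    stop("every matched patient needs a cost breakdown", call. = FALSE)
  }
  list(tc = as.numeric(tc), cs = as.numeric(cs))
}

#' Incremental cost of the teleconsultation group
#'
#' Difference of group mean total costs over the matched sample.
#'
#' @param matched a [match_1to1()] result.
#' @param costs per-patient cost table from [patient_total_cost()].
#' @return an object of class `incremental_cost_result` with
#'   `mean_total_tc`, `mean_total_cs`, `incremental` (euros) and the group
#'   cost vectors (used by the bootstrap).
#' @export
incremental_cost <- function(matched, costs) {
  v <- matched_costs(matched, costs)
  if (!length(v$tc)) stop("empty matched sample", call. = FALSE)
  structure(list(
    mean_total_tc = mean(v$tc),
    mean_total_cs = mean(v$cs),
    incremental = mean(v$tc) - mean(v$cs),
    costs_tc = v$tc, costs_cs = v$cs,
    n_pairs = length(v$tc)
  ), class = "incremental_cost_result")
}

#' @export
print.incremental_cost_result <- function(x, ...) {
  cat(sprintf("Incremental cost: %.2f = %.2f (TC) - %.2f (CS), %d pairs\n",
              x$incremental, x$mean_total_tc, x$mean_total_cs, x$n_pairs))
  if (!is.null(x$bootstrap_ci)) {
    cat(sprintf("  %d-replicate bootstrap 95%% CI: (%.2f, %.2f)\n",
                x$n_bootstrap, x$bootstrap_ci[1L], x$bootstrap_ci[2L]))
  }
  invisible(x)
}

#' Bootstrap percentile interval for the incremental cost
#'
#' Non-parametric bootstrap: patients are resampled with replacement within
#' each matched group (not as pairs), the incremental cost is recomputed per
#' replicate, and the percentile interval is returned. Deterministic given
#' `seed`.
#'
#' @param costs_tc,costs_cs matched-group total-cost vectors, or an
#'   `incremental_cost_result` as first argument.
#' @param B number of bootstrap replications.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list with `ci` (low, high), `replicates`, `B`, `seed`.
#' @export
bootstrap_incremental <- function(costs_tc, costs_cs = NULL, B = 1000,
                                  seed = 1L, conf = 0.95) {
  if (inherits(costs_tc, "incremental_cost_result")) {
    costs_cs <- costs_tc$costs_cs
    costs_tc <- costs_tc$costs_tc
  }
  if (B < 1) stop("'B' must be >= 1", call. = FALSE)
  n1 <- length(costs_tc); n0 <- length(costs_cs)
  set.seed(derive_seed(seed, "bootstrap"))
  m1 <- matrix(sample.int(n1, n1 * B, replace = TRUE), nrow = B)
  m0 <- matrix(sample.int(n0, n0 * B, replace = TRUE), nrow = B)
  reps <- rowMeans(matrix(costs_tc[m1], nrow = B)) -
    rowMeans(matrix(costs_cs[m0], nrow = B))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))
  list(ci = ci, replicates = reps, B = as.integer(B), seed = seed)
}

#' Attach a bootstrap interval to an incremental-cost result
#' @param result an `incremental_cost_result`.
#' @inheritParams bootstrap_incremental
#' @return the result with `bootstrap_ci`, `n_bootstrap`, `seed` filled in.
#' @export
add_bootstrap_ci <- function(result, B = 1000, seed = 1L, conf = 0.95) {
  bs <- bootstrap_incremental(result, B = B, seed = seed, conf = conf)
  result$bootstrap_ci <- bs$ci
  result$n_bootstrap <- bs$B
  result$seed <- seed
  result
}

# names a tornado scenario may modify
tornado_modifiable <- function() {
  setdiff(names(formals(cost_inputs)), character(0))
}

# rebuild a cost_inputs with modifications applied
modify_inputs <- function(inputs, mods) {
  if (length(mods)) {
    bad <- setdiff(names(mods), tornado_modifiable())
    if (length(bad)) {
      stop("unknown cost parameter(s): ", paste(bad, collapse = ", "),
           "; valid names are: ", paste(tornado_modifiable(), collapse = ", "),
           call. = FALSE)
    }
  }
  args <- unclass(inputs)
  args[names(mods)] <- mods
  do.call(cost_inputs, args)
}

#' Tornado deterministic sensitivity analysis
#'
#' Recomputes the matched incremental cost under one-at-a-time parameter
#' modifications and sorts scenarios by the absolute deviation from the
#' base. The base row reproduces the unmodified incremental cost exactly.
#'
#' @param pop the population the matched sample was drawn from (costs are
#'   recomputed from it under each scenario).
#' @param matched a [match_1to1()] result.
#' @param inputs the base [cost_inputs()].
#' @param scenarios named list of modification lists, e.g.
#'   `list("free software" = list(software_monthly_per_user = 0))`. The
#'   default set varies the medically-transported share (0 and 1), the
#'   amortisation period (10 years), the software cost (free), the station
#'   fleet size and the observed TC volume.
#' @return a `data.frame` with `label`, `incremental`, `deviation`, sorted
#'   by `|deviation|` descending (base row first carries deviation 0).
#' @export
tornado <- function(pop, matched, inputs = cost_inputs(),
                    scenarios = default_tornado_scenarios(inputs)) {
  if (!length(scenarios)) stop("scenario list is empty", call. = FALSE)
  base <- incremental_cost(matched, patient_total_cost(pop, inputs))
  rows <- lapply(names(scenarios), function(lb) {
    inc <- incremental_cost(
      matched, patient_total_cost(pop, modify_inputs(inputs, scenarios[[lb]]))
    )$incremental
    data.frame(label = lb, incremental = inc,
               deviation = inc - base$incremental, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$deviation)), , drop = FALSE]
  out <- rbind(data.frame(label = "base", incremental = base$incremental,
                          deviation = 0, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Default tornado scenario set
#' @param inputs base [cost_inputs()] used to derive the varied values.
#' @return named list of modification lists.
#' @export
default_tornado_scenarios <- function(inputs = cost_inputs()) {
  list(
    "no medical transport" = list(share_med_transport = 0),
    "all medical transport" = list(share_med_transport = 1),
    "10-year depreciation" = list(amortization_months = 120),
    "free software" = list(software_monthly_per_user = 0),
    "half the stations" = list(n_stations = inputs$n_stations / 2),
    "double the stations" = list(n_stations = inputs$n_stations * 2),
    "half the TC volume" = list(n_tc_patients_total =
                                  ceiling(inputs$n_tc_patients_total / 2)),
    "double the TC volume" = list(n_tc_patients_total =
                                    inputs$n_tc_patients_total * 2)
  )
}
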