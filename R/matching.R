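# Propensity-score matching: selection into the teleconsultation group is
# covariate-driven, so the matched control group is built from the fitted
# probability of TC membership given covariates.

default_ps_covariates <- c("age", "gender", "travel_time_min",
                           "median_living_std", "pop_density",
                           "pathway_type", "icd10_chapter", "care_unit")

#' Fit the propensity-score logit
#'
#' Maximum-likelihood logistic regression of TC-group membership on patient
#' covariates. Continuous covariates enter linearly; categorical covariates
#' as full indicator sets with one reference level each. Perfect separation
#' is raised as an error (never silently worked around), since a separating
#' covariate defeats the purpose of matching.
#'
#' @param pop a `patient_population` data.frame with a `group` column.
#' @param covariates character vector of covariate column names.
#' @return an object of class `propensity_model` with elements
#'   `coefficients`, `scores` (fitted probabilities, strictly inside (0,1)),
#'   `converged`, `log_likelihood` and the fitted `glm` object.
#' @export
fit_propensity <- function(pop, covariates = default_ps_covariates) {
  stopifnot(is.data.frame(pop), "group" %in% names(pop))
  if (!all(c("TC", "CS") %in% pop$group)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  missing_cols <- setdiff(covariates, names(pop))
  if (length(missing_cols)) {
    stop("missing covariate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat <- pop[, covariates, drop = FALSE]
  # drop constant columns (no information, would break model.matrix)
  keep <- vapply(dat, function(x) length(unique(x)) > 1L, logical(1))
  dat <- dat[, keep, drop = FALSE]
  dat$.treat <- as.integer(pop$group == "TC")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.treat ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  scores <- pmin(pmax(stats::fitted(fit), .Machine$double.eps),
                 1 - .Machine$double.eps)
  # Boundary fitted values alone are expected when some category level has
  # no treated patients (as in the source cohort); the fit only fails when
  # the score actually classifies the groups perfectly, which defeats
  # matching.
  if (separation &&
      min(scores[dat$.treat == 1L]) >= max(scores[dat$.treat == 0L])) {
    stop("perfect separation detected in the propensity logit: the score ",
         "classifies the groups exactly; review the covariate set rather ",
         "than relying on a degenerate score", call. = FALSE)
  }
  structure(list(
    coefficients = stats::coef(fit),
    scores = scores,
    converged = fit$converged,
    log_likelihood = as.numeric(stats::logLik(fit)),
    fit = fit
  ), class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("Propensity-score logit: %d coefficients, logLik %.2f, %s\n",
              length(x$coefficients), x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Standardized mean difference between two groups
#'
#' Difference in means over the pooled standard deviation; the assertable
#' balance criterion (unlike p-values it does not shrink with n).
#'
#' @param x numeric vector (indicator for categorical levels).
#' @param treated logical vector, same length.
#' @return a single number; 0 when either group is empty or both are
#'   constant.
#' @export
smd <- function(x, treated) {
  x1 <- x[treated]; x0 <- x[!treated]
  if (!length(x1) || !length(x0)) return(0)
  s <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mean(x1) - mean(x0)) / s
}

# expand a covariate into numeric columns (indicators for categories)
covariate_columns <- function(pop, covariate) {
  x <- pop[[covariate]]
  if (is.numeric(x)) {
    stats::setNames(list(x), covariate)
  } else {
    lv <- sort(unique(x))
    cols <- lapply(lv, function(l) as.numeric(x == l))
    stats::setNames(cols, paste(covariate, lv, sep = ":"))
  }
}

#' Covariate balance table
#'
#' Per-covariate (and per-category) group means, standardized mean
#' differences and two-sample test p-values: Welch t-tests for continuous
#' covariates, proportion tests for category indicators.
#'
#' @param pop a `patient_population` data.frame.
#' @param covariates covariate column names.
#' @return a `data.frame` with columns `covariate`, `mean_tc`, `mean_cs`,
#'   `smd` and `p_value`.
#' @export
balance_table <- function(pop, covariates = default_ps_covariates) {
  treated <- pop$group == "TC"
  rows <- list()
  for (cv in covariates) {
    for (nm in names(cols <- covariate_columns(pop, cv))) {
      x <- cols[[nm]]
      p <- tryCatch({
        if (is.numeric(pop[[cv]])) {
          stats::t.test(x[treated], x[!treated])$p.value
        } else {
          k <- c(sum(x[treated]), sum(x[!treated]))
          n <- c(sum(treated), sum(!treated))
          if (any(k == 0) && sum(k) == 0) NA_real_
          else suppressWarnings(stats::prop.test(k, n)$p.value)
        }
      }, error = function(e) NA_real_)
      rows[[nm]] <- data.frame(covariate = nm,
                               mean_tc = mean(x[treated]),
                               mean_cs = mean(x[!treated]),
                               smd = smd(x, treated),
                               p_value = p,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 1:1 nearest-neighbour propensity-score matching
#'
#' Greedy matching without replacement: TC patients are processed in
#' descending propensity-score order (ties broken by smallest patient id)
#' and each is paired with the closest unmatched CS patient (distance ties
#' again broken by smallest patient id). No caliper by default; with a
#' caliper, TC patients whose nearest available control lies outside it are
#' left unmatched.
#'
#' @param pop a `patient_population` data.frame.
#' @param scores fitted propensity scores, one per row of `pop` (e.g.
#'   `fit_propensity(pop)$scores`).
#' @param caliper optional maximum score distance for an admissible pair.
#' @return an object of class `matched_sample`: `pairs` (data.frame with
#'   `tc_id`, `cs_id`, `tc_score`, `cs_score`), `unmatched_tc_ids`,
#'   `balance_before`, `balance_after`, and `matched_ids`.
#' @export
match_1to1 <- function(pop, scores, caliper = NULL) {
  stopifnot(length(scores) == nrow(pop))
  treated <- pop$group == "TC"
  if (sum(!treated) < sum(treated)) {
    stop("fewer CS than TC patients: 1:1 matching without replacement ",
         "is impossible", call. = FALSE)
  }
  ids <- pop$patient_id
  tc_idx <- which(treated)
  tc_idx <- tc_idx[order(-scores[tc_idx], ids[tc_idx])]
  cs_idx <- which(!treated)
  cs_scores <- scores[cs_idx]
  cs_ids <- ids[cs_idx]
  available <- rep(TRUE, length(cs_idx))
  pair_tc <- integer(0); pair_cs <- integer(0)
  unmatched <- integer(0)
  for (i in tc_idx) {
    d <- abs(cs_scores - scores[i])
    d[!available] <- Inf
    j <- which(d == min(d))
    if (length(j) > 1L) j <- j[which.min(cs_ids[j])]
    if (!is.finite(d[j]) || (!is.null(caliper) && d[j] > caliper)) {
      unmatched <- c(unmatched, ids[i])
      next
    }
    available[j] <- FALSE
    pair_tc <- c(pair_tc, i)
    pair_cs <- c(pair_cs, cs_idx[j])
  }
  pairs <- data.frame(tc_id = ids[pair_tc], cs_id = ids[pair_cs],
                      tc_score = scores[pair_tc], cs_score = scores[pair_cs])
  matched_rows <- c(pair_tc, pair_cs)
  matched <- pop[matched_rows, , drop = FALSE]
  structure(list(
    pairs = pairs,
    unmatched_tc_ids = unmatched,
    matched_ids = ids[matched_rows],
    balance_before = balance_table(pop,
                                   intersect(default_ps_covariates, names(pop))),
    balance_after = balance_table(matched,
                                  intersect(default_ps_covariates, names(pop))),
    score_smd_before = smd(scores, treated),
    score_smd_after = smd(scores[matched_rows],
                          pop$group[matched_rows] == "TC")
  ), class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("Matched sample: %d pairs (%d TC unmatched)\n",
              nrow(x$pairs), length(x$unmatched_tc_ids)))
  cat(sprintf("  propensity-score SMD: %.3f before, %.3f after\n",
              x$score_smd_before, x$score_smd_after))
  cat(sprintf("  max |covariate SMD| after matching: %.3f\n",
              max(abs(x$balance_after$smd))))
  invisible(x)
}
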