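test_that("propensity logit recovers the closed-form 2x2 log odds ratio", {
  # x = 0: 10 treated, 30 controls; x = 1: 30 treated, 10 controls
  pop <- data.frame(
    patient_id = 1:80,
    x = c(rep(0, 40), rep(1, 40)),
    group = c(rep("TC", 10), rep("CS", 30), rep("TC", 30), rep("CS", 10))
  )
  fit <- fit_propensity(pop, covariates = "x")
  expect_equal(unname(fit$coefficients["x"]), log(9), tolerance = 1e-6)
  expect_true(all(fit$scores > 0 & fit$scores < 1))
  expect_true(is.finite(fit$log_likelihood))
})

test_that("glm scores agree with a brute-force likelihood grid search", {
  set.seed(42)
  n <- 60
  x <- rnorm(n)
  pr <- plogis(-0.5 + 1.2 * x)
  pop <- data.frame(patient_id = 1:n, x = x,
                    group = ifelse(runif(n) < pr, "TC", "CS"))
  y <- as.integer(pop$group == "TC")
  negll <- function(a, b) -sum(y * (a + b * x) - log1p(exp(a + b * x)))
  # two-stage grid refinement around the coarse optimum
  grid_opt <- function(ar, br) {
    g <- expand.grid(a = ar, b = br)
    g[which.min(mapply(negll, g$a, g$b)), ]
  }
  o1 <- grid_opt(seq(-4, 4, 0.05), seq(-4, 4, 0.05))
  o2 <- grid_opt(seq(o1$a - 0.05, o1$a + 0.05, 0.0005),
                 seq(o1$b - 0.05, o1$b + 0.05, 0.0005))
  fit <- fit_propensity(pop, covariates = "x")
  oracle_scores <- plogis(o2$a + o2$b * x)
  expect_lt(max(abs(fit$scores - oracle_scores)), 1e-4)
})

test_that("a perfectly separating covariate raises an error", {
  pop <- data.frame(patient_id = 1:40, x = c(rnorm(20, 10), rnorm(20, -10)),
                    group = rep(c("TC", "CS"), each = 20))
  expect_error(fit_propensity(pop, covariates = "x"), "separation")
})

test_that("greedy nearest-neighbour matching follows the documented order", {
  pop <- data.frame(patient_id = 1:5,
                    group = c("TC", "TC", "CS", "CS", "CS"))
  scores <- c(0.9, 0.5, 0.85, 0.55, 0.1)
  m <- match_1to1(pop, scores)
  expect_equal(m$pairs$tc_id, c(1L, 2L))
  expect_equal(m$pairs$cs_id, c(3L, 4L))

  # identical scores: ties broken by smallest patient id, full pairing
  pop2 <- data.frame(patient_id = 1:6,
                     group = rep(c("TC", "CS"), each = 3))
  m2 <- match_1to1(pop2, rep(0.5, 6))
  expect_equal(m2$pairs$tc_id, 1:3)
  expect_equal(m2$pairs$cs_id, 4:6)
  # each control used at most once
  expect_false(anyDuplicated(m2$pairs$cs_id) > 0)

  expect_error(
    match_1to1(data.frame(patient_id = 1:3,
                          group = c("TC", "TC", "CS")), c(0.5, 0.4, 0.5)),
    "fewer CS")
})

test_that("matching restores covariate balance under strong selection", {
  pop <- test_population_large()
  fit <- fit_propensity(pop)
  m <- match_1to1(pop, fit$scores)
  expect_gt(max(abs(m$balance_before$smd)), 0.1)
  expect_lt(max(abs(m$balance_after$smd)), 0.1)
  # matching never worsens the score imbalance itself
  expect_lte(abs(m$score_smd_after), abs(m$score_smd_before))
})

test_that("a caliper leaves distant treated patients unmatched", {
  pop <- data.frame(patient_id = 1:4, group = c("TC", "TC", "CS", "CS"))
  m <- match_1to1(pop, c(0.9, 0.2, 0.21, 0.19), caliper = 0.05)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$unmatched_tc_ids, 1L)
})
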