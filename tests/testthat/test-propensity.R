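# Propensity model, IPTW weights and balance diagnostics.

test_that("intercept-only model recovers the empirical arm share", {
  set.seed(1)
  r <- make_records(time = rexp(400, 0.1) + 0.01, event = rbinom(400, 1, 0.5),
                    arm = rbinom(400, 1, 0.3), one = rep(1, 400))
  # a degenerate covariate is dropped, leaving the intercept
  fit <- suppressWarnings(fit_propensity(r, "one"))
  expect_equal(unique(round(fit$ps_treat, 12)), round(mean(r$arm), 12))
})

test_that("propensity coefficients recover a known logistic model", {
  p <- default_sim_params(10000)
  r <- simulate_cohort(p, 42)
  fit <- fit_propensity(r, default_covs)
  truth <- c(p$treatment$intercept, p$treatment$coef)
  mm <- model.matrix(~ age_z + sex_male + hypertension, data = as.data.frame(r))
  W <- diag(as.vector(fit$ps_treat * (1 - fit$ps_treat)))
  se <- sqrt(diag(solve(t(mm) %*% W %*% mm)))
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
  # score equation: fitted probabilities sum to the arm-1 count
  expect_equal(sum(fit$ps_treat), sum(r$arm), tolerance = 1e-6)
})

test_that("a covariate identically distributed across arms gets a near-zero coefficient", {
  set.seed(7)
  n <- 10000
  r <- make_records(time = rexp(n, 0.1) + 0.01, event = rep(0L, n),
                    arm = rbinom(n, 1, 0.5), x = rnorm(n))
  fit <- fit_propensity(r, "x")
  se <- sqrt(1 / (n * 0.25))  # information bound for a standard normal covariate
  expect_lt(abs(fit$coefficients[["x"]]), 3 * se)
})

test_that("weight formulas match their definitions", {
  fit <- structure(list(ps_actual = c(0.25, 0.4), ps_treat = c(0.25, 0.4),
                        marginal = c(`0` = 0.2, `1` = 0.8),
                        arm = c(1, 1)), class = "propensity_fit")
  expect_equal(compute_weights(fit, "ATE", stabilized = FALSE)$w, c(4, 2.5))
  expect_equal(compute_weights(fit, "ATE", stabilized = TRUE)$w, c(0.8 / 0.25, 0.8 / 0.4))
  # constant ps equal to arm share: stabilized weights exactly 1
  fit2 <- structure(list(ps_actual = rep(0.7, 5), ps_treat = rep(0.7, 5),
                         marginal = c(`0` = 0.3, `1` = 0.7),
                         arm = rep(1, 5)), class = "propensity_fit")
  expect_equal(compute_weights(fit2, "ATE", TRUE)$w, rep(1, 5))
  # ATT: treated 1, comparator ps/(1-ps)
  fit3 <- structure(list(ps_actual = c(0.4, 0.75), ps_treat = c(0.4, 0.25),
                         marginal = c(`0` = 0.5, `1` = 0.5),
                         arm = c(1, 0)), class = "propensity_fit")
  expect_equal(compute_weights(fit3, "ATT")$w, c(1, 0.25 / 0.75))
  expect_error(compute_weights(structure(list(ps_actual = c(0, 0.5), arm = c(1, 0),
                                              ps_treat = c(0, 0.5),
                                              marginal = c(`0` = 0.5, `1` = 0.5)),
                                         class = "propensity_fit"), "ATE"),
               "positivity")
})

test_that("standardized mean differences follow their definition", {
  r <- make_records(time = rep(1, 200), event = rep(0L, 200),
                    arm = rep(0:1, each = 100),
                    x = c(rnorm(100, 0, 1), rnorm(100, 1, 1)))
  smd <- standardized_mean_differences(r, "x")
  s_pool <- sqrt((var(r$x[r$arm == 1]) * 99 / 100 + var(r$x[r$arm == 0]) * 99 / 100) / 2)
  expect_equal(smd$smd, (mean(r$x[r$arm == 1]) - mean(r$x[r$arm == 0])) / s_pool,
               tolerance = 1e-10)
  # identical distributions: all zero; degenerate covariate: zero + flag
  r2 <- make_records(time = rep(1, 10), event = rep(0L, 10), arm = rep(0:1, 5),
                     x = rep(2, 10), g = factor(rep("a", 10)))
  smd2 <- standardized_mean_differences(r2, c("x", "g"))
  expect_true(all(smd2$smd == 0))
  expect_true(all(smd2$degenerate))
})

test_that("stabilized ATE weighting balances a confounded cohort", {
  r <- simulate_cohort(default_sim_params(5000), 14)
  pre <- standardized_mean_differences(r, default_covs)
  fit <- fit_propensity(r, default_covs)
  w <- compute_weights(fit, "ATE", TRUE)
  post <- standardized_mean_differences(r, default_covs, weights = w)
  expect_gt(max(abs(pre$smd)), 0.1)  # confounding is real
  expect_lt(max(abs(post$smd)), 0.1)
  expect_equal(length(w$w), nrow(r))  # weighting never drops subjects
})

test_that("perfect separation is reported as an error", {
  r <- make_records(time = rep(1, 40), event = rep(0L, 40),
                    arm = rep(0:1, each = 20), x = c(rnorm(20, -10), rnorm(20, 10)))
  expect_error(fit_propensity(r, "x"), "separation")
})
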