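# Weighted cause-specific Cox estimation against independent oracles.

library(survival)

test_that("unit-weight fit matches brute-force partial-likelihood maximization", {
  # toy data: treated event at t=1; control events at t=2, 3
  r <- make_records(time = c(1, 2, 3, 4), event = c(1L, 1L, 1L, 0L),
                    arm = c(1L, 0L, 0L, 1L))
  fit <- fit_weighted_cox(r, cause = 1)
  bf <- brute_force_cox(r$time, r$event == 1, r$arm)
  expect_lt(abs(fit$beta[["arm"]] - bf), 1e-6)
})

test_that("weighted fits match brute-force maximization on random small data", {
  set.seed(2024)
  for (i in 1:8) {
    n <- 30
    r <- make_records(time = round(rexp(n, 0.2) + 0.05, 3),
                      event = as.integer(rbinom(n, 1, 0.7)),
                      arm = rbinom(n, 1, 0.5))
    w <- runif(n, 0.3, 3)
    fit <- fit_weighted_cox(r, w, cause = 1)
    bf <- brute_force_cox(r$time, r$event == 1, r$arm, w)
    expect_lt(abs(fit$beta[["arm"]] - bf), 1e-6)
  }
})

test_that("unit-weight fits agree with survival::coxph to high precision", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:50, 1)
    r <- make_records(time = rexp(n, 0.15) + 1e-4,   # continuous: no ties
                      event = as.integer(rbinom(n, 1, 0.6)),
                      arm = rbinom(n, 1, 0.5))
    if (sum(r$event == 1 & r$arm == 1) == 0 || sum(r$event == 1 & r$arm == 0) == 0) next
    fit <- fit_weighted_cox(r, cause = 1)
    cf <- coxph(Surv(time, event == 1) ~ arm, data = as.data.frame(r),
                ties = "breslow", robust = TRUE)
    expect_lt(abs(fit$beta[["arm"]] - coef(cf)[["arm"]]), 1e-6)
    expect_lt(abs(fit$se_robust[["arm"]] - sqrt(cf$var[1, 1])), 1e-6)
  }
})

test_that("adjusted fits agree with multivariate coxph", {
  set.seed(5)
  n <- 300
  r <- make_records(time = rexp(n, 0.2 * exp(0.3 * rbinom(n, 1, 0.5))) + 1e-5,
                    event = as.integer(rbinom(n, 1, 0.7)),
                    arm = rbinom(n, 1, 0.5),
                    age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5))
  w <- runif(n, 0.5, 2)
  fit <- fit_weighted_cox(r, w, cause = 1, adjust = c("age", "sex"))
  cf <- coxph(Surv(time, event == 1) ~ arm + age + sex, data = as.data.frame(r),
              weights = w, ties = "breslow", robust = TRUE)
  expect_equal(unname(fit$beta), unname(coef(cf)), tolerance = 1e-7)
  expect_equal(unname(fit$se_robust), unname(sqrt(diag(cf$var))), tolerance = 1e-7)
})

test_that("identical event-time multisets across arms give beta = 0", {
  tt <- c(1, 2, 3, 5, 8)
  r <- make_records(time = c(tt, tt), event = rep(1L, 10), arm = rep(0:1, each = 5))
  fit <- fit_weighted_cox(r, cause = 1)
  expect_lt(abs(fit$beta[["arm"]]), 1e-8)
})

test_that("beta is invariant to weight scale and antisymmetric under label swap", {
  set.seed(3)
  n <- 150
  r <- make_records(time = rexp(n, 0.2) + 1e-5,
                    event = as.integer(rbinom(n, 1, 0.6)),
                    arm = rbinom(n, 1, 0.5))
  w <- runif(n, 0.5, 2)
  f1 <- fit_weighted_cox(r, w, cause = 1)
  f2 <- fit_weighted_cox(r, w * 7.3, cause = 1)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  swapped <- r; swapped$arm <- 1L - swapped$arm
  f3 <- fit_weighted_cox(event_records(as.data.frame(swapped)), w, cause = 1)
  expect_equal(f3$beta[["arm"]], -f1$beta[["arm"]], tolerance = 1e-7)
  # time-scale invariance
  scaled <- r; scaled$time <- scaled$time * 3.7
  f4 <- fit_weighted_cox(event_records(as.data.frame(scaled)), w, cause = 1)
  expect_equal(f4$beta, f1$beta, tolerance = 1e-9)
})

test_that("degenerate inputs raise informative errors", {
  r <- make_records(time = c(1, 2, 3), event = c(0L, 0L, 0L), arm = c(0L, 1L, 0L))
  expect_error(fit_weighted_cox(r, cause = 1), "no events")
  # monotone likelihood: all events in one arm, ordered before the other arm
  r2 <- make_records(time = c(1, 2, 3, 10, 11, 12),
                     event = c(1L, 1L, 1L, 0L, 0L, 0L),
                     arm = c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_error(fit_weighted_cox(r2, cause = 1), "monotone|diverging")
  r3 <- make_records(time = c(1, 2, 3), event = c(1L, 1L, 0L), arm = c(0L, 1L, 0L))
  expect_error(fit_weighted_cox(r3, weights = c(1, -1, 1), cause = 1), "positive")
})

test_that("Breslow baseline hazard reduces to Nelson-Aalen at beta = 0", {
  set.seed(8)
  n <- 80
  r <- make_records(time = rexp(n, 0.3), event = as.integer(rbinom(n, 1, 0.8)),
                    arm = rep(0L, n))
  fit0 <- structure(list(cause = 1, beta = c(arm = 0)), class = "cscox_fit")
  H <- breslow_cumhaz(r, fit = fit0)
  sf <- survfit(Surv(time, event) ~ 1, data = as.data.frame(r), ctype = 1)
  na <- cumsum(sf$n.event / sf$n.risk)[sf$n.event > 0]
  expect_equal(H$hazard, na, tolerance = 1e-12)
  expect_true(all(diff(H$hazard) >= 0))
  expect_true(all(H$jumps > 0))
})

test_that("Breslow estimator: no events gives the zero function; weight scale cancels", {
  r <- make_records(time = c(1, 2), event = c(2L, 0L), arm = c(0L, 1L))
  fit0 <- structure(list(cause = 1, beta = c(arm = 0)), class = "cscox_fit")
  H <- breslow_cumhaz(r, fit = fit0)
  expect_length(H$time, 0)
  set.seed(10)
  n <- 60
  r2 <- make_records(time = rexp(n, 0.2), event = as.integer(rbinom(n, 1, 0.6)),
                     arm = rbinom(n, 1, 0.5))
  f <- fit_weighted_cox(r2, rep(1, n), cause = 1)
  H1 <- breslow_cumhaz(r2, rep(1, n), f)
  H2 <- breslow_cumhaz(r2, rep(2, n), f)
  expect_equal(H1$hazard, H2$hazard, tolerance = 1e-12)
})

test_that("cause-specific fits treat the competing cause as censoring", {
  set.seed(21)
  n <- 400
  r <- make_records(time = rexp(n, 0.3), event = sample(0:2, n, replace = TRUE),
                    arm = rbinom(n, 1, 0.5))
  f1 <- fit_weighted_cox(r, cause = 1)
  cf <- coxph(Surv(time, event == 1) ~ arm, data = as.data.frame(r), ties = "breslow")
  expect_equal(f1$beta[["arm"]], coef(cf)[["arm"]], tolerance = 1e-7)
  fa <- fit_weighted_cox(r, cause = "all")
  cfa <- coxph(Surv(time, event > 0) ~ arm, data = as.data.frame(r), ties = "breslow")
  expect_equal(fa$beta[["arm"]], coef(cfa)[["arm"]], tolerance = 1e-7)
  expect_equal(fa$n_events, sum(r$event > 0))
})
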