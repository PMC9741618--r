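# Shared fixtures: all built in code at test time.

# minimal covariate-free parameter set with constant hazards
flat_params <- function(n = 1000, h1 = 0.02, h2 = 0.04,
                        hr1 = 1, hr2 = 1,
                        cen_rate = 0, horizon = 1000, run_in = 0) {
  sim_params(
    n_subjects = n,
    hazards = list(dementia = hazard_spec(h1, hr_treatment = hr1),
                   death = hazard_spec(h2, hr_treatment = hr2)),
    treatment = list(intercept = 0, coef = NULL),
    censoring = list(rate = cen_rate, horizon = horizon),
    run_in_years = run_in)
}

# hand-built event records from vectors
make_records <- function(time, event, arm, ...) {
  df <- data.frame(id = seq_along(time), time = time, event = event, arm = arm, ...)
  extra <- setdiff(names(df), c("id", "time", "event", "arm"))
  event_records(df, covariate_names = extra)
}

# brute-force maximizer of the 1-covariate Breslow partial likelihood:
# coarse grid then golden-section refinement, independent of the
# Newton-Raphson engine.
brute_force_cox <- function(time, status, arm, w = rep(1, length(time)),
                            lower = -5, upper = 5, tol = 1e-10) {
  logpl <- function(beta) {
    ll <- 0
    for (u in unique(time[status == 1])) {
      at_risk <- time >= u
      evs <- which(status == 1 & time == u)
      ll <- ll + sum(w[evs] * beta * arm[evs]) -
        sum(w[evs]) * log(sum(w[at_risk] * exp(beta * arm[at_risk])))
    }
    ll
  }
  grid <- seq(lower, upper, length.out = 401)
  vals <- vapply(grid, logpl, numeric(1))
  i <- which.max(vals)
  opt <- optimize(logpl, interval = c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                  maximum = TRUE, tol = tol)
  opt$maximum
}

default_covs <- c("age_z", "sex_male", "hypertension")
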