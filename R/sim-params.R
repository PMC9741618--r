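# Generative model specification for the synthetic cohort generator.
#
# The generator mirrors the causal structure the estimators target:
# baseline covariates C, treatment A drawn from a logistic model given C
# (confounding by indication), two cause-specific proportional hazards
# (cause 1 = dementia onset, cause 2 = death without prior dementia)
# with a known treatment hazard ratio per cause, independent censoring
# (exponential + administrative horizon), and a run-in washout.

#' Covariate specifications for the synthetic generator
#'
#' @param name covariate name.
#' @param mean,sd normal parameters.
#' @param p Bernoulli success probability.
#' @param levels,probs category labels and probabilities.
#' @return a covariate specification list.
#' @export
cov_normal <- function(name, mean = 0, sd = 1) {
  stopifnot(is.character(name), sd > 0)
  list(name = name, dist = "normal", mean = mean, sd = sd)
}

#' @rdname cov_normal
#' @export
cov_bernoulli <- function(name, p) {
  stopifnot(p > 0, p < 1)
  list(name = name, dist = "bernoulli", p = p)
}

#' @rdname cov_normal
#' @export
cov_categorical <- function(name, levels, probs) {
  stopifnot(length(levels) == length(probs), all(probs > 0),
            abs(sum(probs) - 1) < 1e-8)
  list(name = name, dist = "categorical", levels = levels, probs = probs)
}

#' Cause-specific hazard specification
#'
#' Hazards are constant or piecewise-constant in time. The treatment
#' effect is a log hazard ratio, constant by default; a vector (one per
#' time segment) specifies a time-varying effect, used e.g. to generate
#' crossing hazards for diagnostics testing. Covariate effects are log
#' hazard ratios per unit of the (numeric) covariate, or per indicator
#' of a category written as `"name:level"`.
#'
#' @param base baseline rate(s), events per person-year; length
#'   `length(cuts) + 1`.
#' @param cuts interior segment boundaries in years (increasing).
#' @param hr_treatment treatment hazard ratio, scalar or one per segment.
#' @param coef named vector of covariate log hazard ratios.
#' @return hazard specification list.
#' @export
hazard_spec <- function(base, cuts = numeric(0), hr_treatment = 1, coef = NULL) {
  stopifnot(length(base) == length(cuts) + 1L, all(is.finite(base)), all(base >= 0),
            all(diff(cuts) > 0), all(hr_treatment > 0),
            length(hr_treatment) %in% c(1L, length(base)))
  if (length(hr_treatment) == 1L) hr_treatment <- rep(hr_treatment, length(base))
  list(base = base, cuts = cuts, log_hr_treatment = log(hr_treatment),
       coef = coef %||% numeric(0))
}

#' Simulation parameters for the synthetic cohort generator
#'
#' @param n_subjects number of subjects to draw.
#' @param covariates list of covariate specifications
#'   ([cov_normal()], [cov_bernoulli()], [cov_categorical()]).
#' @param treatment list with `intercept` and named `coef` on the
#'   log-odds scale for the probability of initiating treatment arm 1.
#' @param hazards list with elements `dementia` (cause 1) and `death`
#'   (cause 2), each a [hazard_spec()].
#' @param censoring list with `rate` (exponential censoring, per
#'   person-year; 0 disables) and `horizon` (administrative end of
#'   follow-up, years).
#' @param run_in_years washout duration: subjects with a cause-1/2 event
#'   in `(0, run_in_years]` are flagged and removed.
#' @param missingness optional named list of masking rates for
#'   categorical covariates; each element a single rate or a length-2
#'   vector `c(rate_arm0, rate_arm1)` for arm-dependent missingness.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_subjects,
                       covariates = list(),
                       treatment = list(intercept = 0, coef = NULL),
                       hazards,
                       censoring = list(rate = 0, horizon = 12),
                       run_in_years = 1,
                       missingness = NULL) {
  stopifnot(n_subjects >= 1,
            is.list(hazards), all(c("dementia", "death") %in% names(hazards)),
            censoring$rate >= 0, is.finite(censoring$rate),
            censoring$horizon > run_in_years, run_in_years >= 0)
  treatment$coef <- treatment$coef %||% numeric(0)
  p <- structure(list(n_subjects = as.integer(n_subjects),
                      covariates = covariates,
                      treatment = treatment,
                      hazards = hazards,
                      censoring = censoring,
                      run_in_years = run_in_years,
                      missingness = missingness),
                 class = "sim_params")
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  for (hz in p$hazards) {
    if (!all(is.finite(hz$base)) || any(hz$base < 0))
      stop("hazard rates must be finite and nonnegative", call. = FALSE)
  }
  if (!is.finite(p$treatment$intercept) || !all(is.finite(p$treatment$coef)))
    stop("treatment model coefficients must be finite", call. = FALSE)
  invisible(p)
}

#' Default simulation parameters
#'
#' The packaged study conditions for estimator validation: an older
#' type-2-diabetes cohort with confounded treatment assignment (older
#' patients are channelled towards the comparator arm, as observed in
#' both source cohorts), true cause-specific hazard ratios of 0.8 for
#' dementia and 0.6 for death, event rates high enough that both causes
#' are well populated over a 12-year horizon, light random censoring and
#' a 1-year run-in.
#'
#' @param n_subjects cohort size (default 20000).
#' @return a `sim_params` object.
#' @export
default_sim_params <- function(n_subjects = 20000) {
  sim_params(
    n_subjects = n_subjects,
    covariates = list(
      cov_normal("age_z"),              # age standardized: (age - 70) / 8
      cov_bernoulli("sex_male", p = 0.5),
      cov_bernoulli("hypertension", p = 0.6)
    ),
    treatment = list(
      intercept = 0.15,
      coef = c(age_z = -0.4, sex_male = 0.15, hypertension = 0.3)
    ),
    hazards = list(
      dementia = hazard_spec(base = 0.028, hr_treatment = 0.8,
                             coef = c(age_z = 0.05, sex_male = -0.03, hypertension = 0.04)),
      death    = hazard_spec(base = 0.025, hr_treatment = 0.6,
                             coef = c(age_z = 0.05, sex_male = 0.06, hypertension = 0.05))
    ),
    censoring = list(rate = 0.01, horizon = 9),
    run_in_years = 1
  )
}

# linear predictor from a named coefficient vector; entries named
# "covariate:level" are indicators of that category.
linear_predictor <- function(data, coef) {
  lp <- rep(0, nrow(data))
  for (nm in names(coef)) {
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
      if (!parts[1L] %in% names(data))
        stop(sprintf("unknown covariate '%s' in coefficient vector", parts[1L]), call. = FALSE)
      x <- as.numeric(as.character(data[[parts[1L]]]) == parts[2L])
    } else {
      if (!nm %in% names(data))
        stop(sprintf("unknown covariate '%s' in coefficient vector", nm), call. = FALSE)
      x <- as.numeric(data[[nm]])
    }
    lp <- lp + coef[[nm]] * x
  }
  lp
}

draw_covariates <- function(params) {
  n <- params$n_subjects
  out <- list()
  if (!length(params$covariates))
    return(as.data.frame(matrix(numeric(0), nrow = n, ncol = 0L)))
  for (cv in params$covariates) {
    out[[cv$name]] <- switch(cv$dist,
      normal      = rnorm(n, cv$mean, cv$sd),
      bernoulli   = rbinom(n, 1L, cv$p),
      categorical = factor(sample(cv$levels, n, replace = TRUE, prob = cv$probs),
                           levels = cv$levels),
      stop("unknown covariate distribution: ", cv$dist)
    )
  }
  as.data.frame(out, optional = TRUE)
}
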