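# Synthetic competing-risks cohort generator and its ground truth.

#' Construct an analysis-ready event-record set
#'
#' The analysis unit is the quadruplet (T, E, A, C): follow-up time in
#' years, event type (0 censored, 1 dementia, 2 death without prior
#' dementia), treatment arm (0 comparator, 1 active), and baseline
#' covariates.
#'
#' @param data data.frame with columns `time`, `event`, `arm`, plus
#'   covariate columns.
#' @param covariate_names names of the covariate columns.
#' @param truth optional `sim_params` generating truth, carried along
#'   for recovery tests.
#' @return data.frame of class `event_records`.
#' @export
event_records <- function(data, covariate_names = character(0), truth = NULL) {
  stopifnot(is.data.frame(data),
            all(c("time", "event", "arm") %in% names(data)),
            all(covariate_names %in% names(data)))
  if (!all(is.finite(data$time)) || any(data$time <= 0))
    stop("follow-up times must be strictly positive and finite", call. = FALSE)
  if (!all(data$event %in% 0:2))
    stop("event codes must be 0 (censored), 1 (dementia) or 2 (death)", call. = FALSE)
  if (!all(data$arm %in% 0:1))
    stop("arm must be coded 0/1", call. = FALSE)
  structure(data,
            covariate_names = covariate_names,
            truth = truth,
            class = c("event_records", "data.frame"))
}

#' @export
print.event_records <- function(x, ...) {
  cat(sprintf("Event records: %d subjects (%d arm 1 / %d arm 0); events: %d dementia, %d death, %d censored\n",
              nrow(x), sum(x$arm == 1), sum(x$arm == 0),
              sum(x$event == 1), sum(x$event == 2), sum(x$event == 0)))
  if (length(attr(x, "covariate_names")))
    cat("Covariates:", paste(attr(x, "covariate_names"), collapse = ", "), "\n")
  invisible(x)
}

# piecewise-constant cause-specific rates per subject.
# Returns boundaries b (b[1] = 0) and n x S rate matrices for each cause.
subject_rates <- function(params, arm, covariate_data) {
  hz1 <- params$hazards$dementia
  hz2 <- params$hazards$death
  cuts <- sort(unique(c(hz1$cuts, hz2$cuts)))
  b <- c(0, cuts)
  seg_rate <- function(hz) {
    # rate of this cause in each merged segment
    seg_of <- findInterval(b, hz$cuts) + 1L
    base <- hz$base[seg_of]
    lhr <- hz$log_hr_treatment[seg_of]
    mult <- exp(linear_predictor(covariate_data, hz$coef))
    outer(mult, base) * exp(outer(arm, lhr)) # n x S
  }
  list(b = b, r1 = seg_rate(hz1), r2 = seg_rate(hz2))
}

# inverse-transform event times on the total hazard, with multinomial
# cause allocation proportional to the cause-specific hazards at the
# event time; exact for piecewise-constant hazards.
draw_event_times <- function(rates, e_std, u_cause) {
  b <- rates$b
  S <- length(b)
  n <- nrow(rates$r1)
  R <- rates$r1 + rates$r2
  widths <- diff(c(b, Inf))
  t_ev <- rep(Inf, n)
  seg_ev <- rep(NA_integer_, n)
  h_prev <- rep(0, n)
  remaining <- rep(TRUE, n)
  for (s in seq_len(S)) {
    rs <- R[, s]
    inc <- rs * widths[s]
    hit <- remaining & (e_std <= h_prev + inc) & rs > 0
    t_ev[hit] <- b[s] + (e_std[hit] - h_prev[hit]) / rs[hit]
    seg_ev[hit] <- s
    remaining <- remaining & !hit
    h_prev <- h_prev + ifelse(is.finite(inc), inc, 0)
  }
  idx <- cbind(seq_len(n), ifelse(is.na(seg_ev), 1L, seg_ev))
  p1 <- ifelse(R[idx] > 0, rates$r1[idx] / R[idx], 0)
  cause <- ifelse(u_cause <= p1, 1L, 2L)
  list(time = t_ev, cause = cause)
}

apply_missingness <- function(data, arm, missingness) {
  for (nm in names(missingness)) {
    rate <- missingness[[nm]]
    if (length(rate) == 1L) rate <- c(rate, rate)
    x <- data[[nm]]
    if (!is.factor(x)) x <- factor(x)
    lev <- c(levels(x), "missing")
    x <- factor(as.character(x), levels = lev)
    mask <- runif(length(x)) < rate[arm + 1L]
    x[mask] <- "missing"
    data[[nm]] <- droplevels(x, exclude = NULL)
    data[[nm]] <- factor(as.character(data[[nm]]), levels = lev)
  }
  data
}

#' Simulate an analysis-ready competing-risks cohort
#'
#' Draws covariates, assigns treatment from the logistic model given
#' covariates, draws the event time from the total cause-specific
#' hazard by inverse transform with the cause allocated proportionally
#' to the cause-specific hazards at that time, applies independent
#' censoring (exponential rate and administrative horizon), and removes
#' subjects with a dementia/death event inside the run-in window
#' (washout). Subjects censored inside the run-in are retained; they
#' never enter post-landmark risk sets.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; a single seeded stream drives all draws.
#' @return an [event_records()] data.frame with attributes
#'   `truth` (the parameters), `ps_true` (assignment probabilities of
#'   the retained subjects) and `washout_removed` (the flagged subjects).
#' @export
simulate_cohort <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  set.seed(as.integer(seed))
  n <- params$n_subjects
  covs <- draw_covariates(params)
  lp <- params$treatment$intercept + linear_predictor(covs, params$treatment$coef)
  if (!all(is.finite(lp)))
    stop("treatment model produced non-finite log-odds", call. = FALSE)
  ps <- plogis(lp)
  arm <- rbinom(n, 1L, ps)
  rates <- subject_rates(params, arm, covs)
  ev <- draw_event_times(rates, e_std = rexp(n), u_cause = runif(n))
  cen <- if (params$censoring$rate > 0) {
    pmin(rexp(n, params$censoring$rate), params$censoring$horizon)
  } else rep(params$censoring$horizon, n)
  time <- pmin(ev$time, cen)
  event <- ifelse(ev$time <= cen, ev$cause, 0L)
  if (!is.null(params$missingness))
    covs <- apply_missingness(covs, arm, params$missingness)
  df <- cbind(data.frame(id = seq_len(n), time = time, event = event, arm = arm), covs)
  washed <- df$event %in% 1:2 & df$time <= params$run_in_years
  out <- event_records(df[!washed, , drop = FALSE],
                       covariate_names = names(covs), truth = params)
  attr(out, "ps_true") <- ps[!washed]
  attr(out, "washout_removed") <- df[washed, , drop = FALSE]
  out
}

# Gauss-Hermite nodes/weights for integrating f against the standard
# normal density: Golub-Welsch on the Jacobi matrix.
gauss_hermite_normal <- function(n) {
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values * sqrt(2),
       weights = (e$vectors[1L, ])^2)
}

# enumerate the covariate distribution as a weighted grid (exact for
# bernoulli/categorical; Gauss-Hermite for normal); NULL if a
# distribution is not representable.
covariate_quadrature <- function(covariates, n_nodes = 40L) {
  cols <- list(); wts <- list(1)
  for (cv in covariates) {
    g <- switch(cv$dist,
      bernoulli = list(v = c(0, 1), w = c(1 - cv$p, cv$p)),
      categorical = list(v = cv$levels, w = cv$probs),
      normal = {
        gh <- gauss_hermite_normal(n_nodes)
        list(v = cv$mean + cv$sd * gh$nodes, w = gh$weights)
      },
      return(NULL))
    cols[[cv$name]] <- g$v
    wts[[length(wts) + 1L]] <- g$w
  }
  grid <- expand.grid(cols, stringsAsFactors = TRUE)
  # expand.grid varies the first factor fastest; build weights to match
  w <- rep(1, nrow(grid))
  stride <- 1L
  for (j in seq_along(cols)) {
    w <- w * rep(wts[[j + 1L]], each = stride, length.out = nrow(grid))
    stride <- stride * length(cols[[j]])
  }
  list(grid = as.data.frame(grid), weights = w)
}

# CIF under piecewise-constant per-subject hazards, averaged over rows
# of the rate matrices (optionally with row weights). Returns
# list(cif1, cif2, surv): each a length(times) vector of
# covariate-averaged values.
piecewise_cif <- function(rates, times, row_weights = NULL) {
  b <- rates$b
  S <- length(b)
  n <- nrow(rates$r1)
  R <- rates$r1 + rates$r2
  widths <- diff(b)
  # boundary values per subject
  surv_b <- matrix(1, n, S)     # S(b_s) at the *start* of segment s
  cif1_b <- matrix(0, n, S)
  cif2_b <- matrix(0, n, S)
  if (S > 1L) for (s in seq_len(S - 1L)) {
    Rs <- R[, s]
    dec <- exp(-Rs * widths[s])
    frac1 <- ifelse(Rs > 0, rates$r1[, s] / Rs, 0)
    frac2 <- ifelse(Rs > 0, rates$r2[, s] / Rs, 0)
    cif1_b[, s + 1L] <- cif1_b[, s] + frac1 * surv_b[, s] * (1 - dec)
    cif2_b[, s + 1L] <- cif2_b[, s] + frac2 * surv_b[, s] * (1 - dec)
    surv_b[, s + 1L] <- surv_b[, s] * dec
  }
  wm <- if (is.null(row_weights)) mean else {
    rw <- row_weights / sum(row_weights)
    function(x) sum(rw * x)
  }
  cif1 <- cif2 <- sv <- numeric(length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    s <- findInterval(t, b)
    s <- max(1L, s)
    d <- t - b[s]
    Rs <- R[, s]
    dec <- exp(-Rs * d)
    frac1 <- ifelse(Rs > 0, rates$r1[, s] / Rs, 0)
    frac2 <- ifelse(Rs > 0, rates$r2[, s] / Rs, 0)
    cif1[j] <- wm(cif1_b[, s] + frac1 * surv_b[, s] * (1 - dec))
    cif2[j] <- wm(cif2_b[, s] + frac2 * surv_b[, s] * (1 - dec))
    sv[j] <- wm(surv_b[, s] * dec)
  }
  list(cif1 = cif1, cif2 = cif2, surv = sv)
}

#' Ground-truth cumulative incidence under the generative model
#'
#' Computes the single-world (counterfactual) cumulative incidence
#' CIF_a(t, k) implied by a [sim_params()] object: in closed form when
#' the hazards carry no covariate effects; by exact enumeration plus
#' Gauss-Hermite quadrature over the covariate distribution when every
#' covariate is Bernoulli, categorical or normal; otherwise by
#' Monte-Carlo marginalization (method recorded in the `"method"`
#' attribute). With `landmark = L > 0` the returned
#' curve is conditional on being event-free at L,
#' (CIF(t) - CIF(L)) / S(L), which is the estimand targeted by the
#' landmarked estimators.
#'
#' @param params a [sim_params()] object.
#' @param arm counterfactual treatment, 0 or 1.
#' @param cause 1 (dementia) or 2 (death without prior dementia).
#' @param times nonnegative evaluation times in years.
#' @param landmark run-in conditioning time (default 0: unconditional).
#' @param n_mc Monte-Carlo size for covariate marginalization.
#' @param mc_seed seed for the marginalization draw (isolated from the
#'   caller's RNG state).
#' @return vector of probabilities, one per time point.
#' @export
true_cif <- function(params, arm, cause, times, landmark = 0,
                     n_mc = 100000, mc_seed = 194901) {
  stopifnot(inherits(params, "sim_params"), arm %in% 0:1)
  if (!cause %in% 1:2) stop("cause must be 1 or 2", call. = FALSE)
  stopifnot(all(times >= 0), landmark >= 0)
  no_cov_effects <- length(params$hazards$dementia$coef) == 0 &&
    length(params$hazards$death$coef) == 0
  row_w <- NULL
  if (no_cov_effects) {
    covs <- as.data.frame(matrix(numeric(0), nrow = 1L, ncol = 0L))
    rates <- subject_rates(params, arm = arm, covariate_data = covs)
    method <- "closed_form"
  } else if (!is.null(quad <- covariate_quadrature(params$covariates))) {
    covs <- quad$grid
    row_w <- quad$weights
    rates <- subject_rates(params, arm = rep(arm, nrow(covs)), covariate_data = covs)
    method <- "quadrature"
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(mc_seed)
    mc_params <- params
    mc_params$n_subjects <- as.integer(n_mc)
    covs <- draw_covariates(mc_params)
    rates <- subject_rates(params, arm = rep(arm, n_mc), covariate_data = covs)
    method <- "monte_carlo"
  }
  eval_t <- unique(c(times, landmark))
  pc <- piecewise_cif(rates, eval_t, row_weights = row_w)
  cifk <- if (cause == 1) pc$cif1 else pc$cif2
  vals <- cifk[match(times, eval_t)]
  if (landmark > 0) {
    cif_l <- cifk[match(landmark, eval_t)]
    s_l <- pc$surv[match(landmark, eval_t)]
    vals <- pmax(0, (vals - cif_l)) / s_l
    vals[times < landmark] <- 0
  }
  structure(vals, method = method)
}
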