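# Emulation of baseline randomization: propensity scores, stabilized
# inverse-probability-of-treatment weights, and balance diagnostics.

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment arm on main
#' effects of the listed covariates. Categorical covariates (including
#' explicit "missing" levels) are expanded to indicators. Optional
#' base weights (e.g. Bayesian bootstrap weights) enter as prior
#' weights of the likelihood.
#'
#' @param records an [event_records()] data.frame.
#' @param covariate_names covariates entering the model; defaults to
#'   the record set's covariate attribute.
#' @param base_weights optional positive per-subject weights.
#' @return object of class `propensity_fit`: `coefficients`,
#'   `ps_treat` (P(A=1|C)), `ps_actual` (probability of the subject's
#'   actual arm), `marginal` (weighted arm shares), `iter`.
#' @export
fit_propensity <- function(records, covariate_names = NULL, base_weights = NULL) {
  covariate_names <- covariate_names %||% attr(records, "covariate_names")
  if (is.null(covariate_names) || !length(covariate_names))
    stop("no covariates specified for the propensity model", call. = FALSE)
  stopifnot(all(covariate_names %in% names(records)))
  n <- nrow(records)
  bw <- if (is.null(base_weights)) rep(1, n) else as.numeric(base_weights)
  stopifnot(length(bw) == n, all(bw > 0))
  df <- as.data.frame(records)[, covariate_names, drop = FALSE]
  mm <- stats::model.matrix(~ ., data = df)
  keep <- c(TRUE, apply(mm[, -1L, drop = FALSE], 2L, function(col) var(col) > 0))
  mm <- mm[, keep, drop = FALSE]
  y <- as.numeric(records$arm)
  fit <- suppressWarnings(
    glm.fit(mm, y, weights = bw, family = binomial())
  )
  if (!fit$converged)
    stop("propensity-score logistic regression did not converge", call. = FALSE)
  p1 <- fit$fitted.values
  eps <- 1e-8
  if (any(p1 < eps | p1 > 1 - eps)) {
    co <- fit$coefficients[-1L]
    worst <- names(co)[which.max(abs(co))]
    stop(sprintf(paste0("fitted propensities numerically at 0/1 ",
                        "(possible perfect separation; largest coefficient: %s)"),
                 worst), call. = FALSE)
  }
  marg1 <- sum(bw * y) / sum(bw)
  structure(list(coefficients = fit$coefficients,
                 ps_treat = p1,
                 ps_actual = ifelse(y == 1, p1, 1 - p1),
                 marginal = c(`0` = 1 - marg1, `1` = marg1),
                 covariate_names = covariate_names,
                 iter = fit$iter,
                 arm = y),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("Propensity fit: %d subjects, marginal P(A=1) = %.3f, %d coefficients\n",
              length(x$ps_treat), x$marginal["1"], length(x$coefficients)))
  invisible(x)
}

#' Inverse-probability-of-treatment weights
#'
#' ATE weights are 1/ps of the actual arm; stabilized ATE weights are
#' multiplied by the marginal arm share, P(A = a_i)/P(A = a_i | C),
#' so that with a constant propensity equal to the arm share every
#' weight is exactly 1. ATT weights are 1 for treated subjects and the
#' propensity odds ps/(1 - ps) for comparators (the standard form; the
#' `stabilized` flag has no effect on ATT weights). Extreme weights
#' (> 10) trigger a warning, never truncation.
#'
#' @param fit a [fit_propensity()] result.
#' @param estimand `"ATE"` or `"ATT"`.
#' @param stabilized logical; multiply ATE weights by marginal arm
#'   shares (default TRUE).
#' @return object of class `weight_vector`: `w`, `estimand`,
#'   `stabilized`.
#' @export
compute_weights <- function(fit, estimand = c("ATE", "ATT"), stabilized = TRUE) {
  stopifnot(inherits(fit, "propensity_fit"))
  estimand <- match.arg(estimand)
  ps <- fit$ps_actual
  if (any(ps <= 0 | ps >= 1))
    stop("propensity scores outside (0,1): positivity violation", call. = FALSE)
  if (estimand == "ATE") {
    w <- 1 / ps
    if (stabilized) w <- w * fit$marginal[as.character(fit$arm)]
  } else {
    w <- ifelse(fit$arm == 1, 1, fit$ps_treat / (1 - fit$ps_treat))
  }
  w <- as.numeric(w)
  if (max(w) > 10)
    warning(sprintf("extreme weight detected (max = %.2f); no truncation applied", max(w)))
  structure(list(w = w, estimand = estimand, stabilized = stabilized),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("%s%s weights: n = %d, mean = %.3f, range [%.3f, %.3f]\n",
              x$estimand, if (x$stabilized) " stabilized" else "",
              length(x$w), mean(x$w), min(x$w), max(x$w)))
  invisible(x)
}

#' Standardized mean differences between treatment arms
#'
#' Continuous covariates: difference in (weighted) means over the
#' pooled standard deviation. Categorical covariates: per-level
#' prevalence difference over the pooled binary standard deviation.
#' Degenerate covariates (zero pooled SD) report SMD 0 with a flag.
#'
#' @param records an [event_records()] data.frame.
#' @param covariate_names covariates to assess.
#' @param weights optional [compute_weights()] result or numeric vector.
#' @return data.frame with columns `covariate`, `level`, `smd`,
#'   `degenerate`.
#' @export
standardized_mean_differences <- function(records, covariate_names = NULL,
                                          weights = NULL) {
  covariate_names <- covariate_names %||% attr(records, "covariate_names")
  w <- resolve_weights(weights, nrow(records))
  a <- records$arm
  rows <- list()
  smd_row <- function(x1, x0, w1, w0, cov, lev) {
    m1 <- weighted_mean(x1, w1); m0 <- weighted_mean(x0, w0)
    s2 <- (weighted_var(x1, w1) + weighted_var(x0, w0)) / 2
    deg <- s2 <= .Machine$double.eps
    data.frame(covariate = cov, level = lev,
               smd = if (deg) 0 else (m1 - m0) / sqrt(s2),
               degenerate = deg, stringsAsFactors = FALSE)
  }
  for (cv in covariate_names) {
    x <- records[[cv]]
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      for (lev in levels(x)) {
        ind <- as.numeric(x == lev)
        rows[[length(rows) + 1L]] <-
          smd_row(ind[a == 1], ind[a == 0], w[a == 1], w[a == 0], cv, lev)
      }
    } else {
      rows[[length(rows) + 1L]] <-
        smd_row(as.numeric(x)[a == 1], as.numeric(x)[a == 0],
                w[a == 1], w[a == 0], cv, NA_character_)
    }
  }
  do.call(rbind, rows)
}
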