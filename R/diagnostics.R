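# Proportional-hazards diagnostics and subgroup analyses.

#' Proportional-hazards diagnostics for the treatment effect
#'
#' Three complementary checks of the proportional-hazards assumption
#' for one cause: (i) the global test based on scaled Schoenfeld
#' residuals (via [survival::cox.zph()]), (ii) a weighted log-rank
#' test (the score test of the weighted partial likelihood at beta =
#' 0; the classical log-rank test under unit weights), and (iii)
#' per-arm log cumulative-hazard curves, whose approximate parallelism
#' on the log-time scale is the graphical check.
#'
#' @param records an [event_records()] data.frame.
#' @param weights optional [compute_weights()] result or numeric vector.
#' @param cause 1, 2 or `"all"`.
#' @return list of class `ph_diagnostics`: `schoenfeld_global_p`,
#'   `logrank_p`, `logrank_chisq`, and `log_cumhaz` (per arm:
#'   `time`, `log_H`).
#' @export
ph_diagnostics <- function(records, weights = NULL, cause = 1) {
  status <- cause_status(records, cause)
  if (sum(status) < 2L) stop("fewer than 2 events of the requested cause", call. = FALSE)
  w <- resolve_weights(weights, nrow(records))
  df <- data.frame(time = records$time, status = status,
                   arm = as.numeric(records$arm), w = w)
  cfit <- survival::coxph(survival::Surv(time, status) ~ arm, data = df,
                          weights = w, ties = "breslow")
  zph <- survival::cox.zph(cfit, global = TRUE)
  sch_p <- zph$table["GLOBAL", "p"]
  lr <- cox_score_test(df$time, df$status, matrix(df$arm, ncol = 1), w)
  log_ch <- lapply(0:1, function(a) {
    sel <- df$arm == a
    ord <- order(df$time[sel])
    tt <- df$time[sel][ord]; ss <- df$status[sel][ord]; ww <- w[sel][ord]
    ev <- which(ss == 1)
    if (!length(ev)) return(list(time = numeric(0), log_H = numeric(0)))
    u <- unique(tt[ev])
    first <- findInterval(u, tt, left.open = TRUE) + 1L
    dsum <- as.vector(rowsum(ww[ev], match(tt[ev], u)))
    H <- cumsum(dsum / revcumsum(ww)[first])
    list(time = u, log_H = log(H))
  })
  structure(list(schoenfeld_global_p = unname(sch_p),
                 logrank_p = lr$p_value,
                 logrank_chisq = lr$statistic,
                 log_cumhaz = list(arm0 = log_ch[[1L]], arm1 = log_ch[[2L]])),
            class = "ph_diagnostics")
}

#' @export
print.ph_diagnostics <- function(x, ...) {
  cat(sprintf("PH diagnostics: Schoenfeld global p = %.4g; weighted log-rank p = %.4g\n",
              x$schoenfeld_global_p, x$logrank_p))
  invisible(x)
}

#' Subgroup analyses with per-stratum reweighting
#'
#' Within each stratum, the propensity model is refit, weights are
#' recomputed, and the weighted cause-specific Cox model is refit, so
#' covariate balance is re-established independently per stratum.
#' Covariates that are constant within a stratum (e.g. the stratifying
#' covariate itself) are dropped from that stratum's propensity model.
#'
#' @param records an [event_records()] data.frame.
#' @param strata a factor (or vector coercible to one) of length
#'   `nrow(records)` defining the partition, or the name of a column.
#' @param covariate_names propensity-model covariates.
#' @param estimand,stabilized passed to [compute_weights()].
#' @param cause passed to [fit_weighted_cox()].
#' @return data.frame with one row per stratum: `stratum`, `n`,
#'   `n_events`, `beta`, `hr`, `se_robust`, `ci_lower`, `ci_upper`,
#'   `wald_p`, `flagged` (TRUE when the stratum had no events or the
#'   fit failed).
#' @export
subgroup_analysis <- function(records, strata, covariate_names = NULL,
                              estimand = "ATE", stabilized = TRUE, cause = 1) {
  covariate_names <- covariate_names %||% attr(records, "covariate_names")
  if (is.character(strata) && length(strata) == 1L) {
    stopifnot(strata %in% names(records))
    strata <- records[[strata]]
  }
  strata <- factor(strata)
  stopifnot(length(strata) == nrow(records))
  rows <- lapply(levels(strata), function(lev) {
    sel <- strata == lev
    sub <- event_records(as.data.frame(records)[sel, , drop = FALSE],
                         covariate_names = covariate_names)
    res <- tryCatch({
      pf <- fit_propensity(sub, covariate_names)
      wt <- suppressWarnings(compute_weights(pf, estimand, stabilized))
      fit <- fit_weighted_cox(sub, wt, cause = cause)
      data.frame(stratum = lev, n = nrow(sub), n_events = fit$n_events,
                 beta = fit$beta[["arm"]], hr = fit$hr[["arm"]],
                 se_robust = fit$se_robust[["arm"]],
                 ci_lower = fit$ci["arm", "lower"],
                 ci_upper = fit$ci["arm", "upper"],
                 wald_p = fit$wald_p[["arm"]],
                 flagged = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(stratum = lev, n = sum(sel),
                 n_events = sum(cause_status(records, cause)[sel]),
                 beta = NA_real_, hr = NA_real_, se_robust = NA_real_,
                 ci_lower = NA_real_, ci_upper = NA_real_, wald_p = NA_real_,
                 flagged = TRUE, stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}
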