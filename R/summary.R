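# Cohort summary tables and their arithmetic self-check.

#' Per-arm cohort summary
#'
#' One row per arm: subject count, events by type with percentages
#' (one decimal), total person-years (summed from baseline), and
#' median follow-up. Covariate distributions are reported with the
#' valid-percentage convention: percentages of categorical levels are
#' taken out of subjects without missing information, with the
#' missing share reported separately.
#'
#' @param records an [event_records()] data.frame.
#' @return object of class `cohort_summary`: list with `events` (per-
#'   arm data.frame) and `covariates` (long data.frame).
#' @export
cohort_summary <- function(records) {
  stopifnot(nrow(records) > 0)
  ev_rows <- lapply(0:1, function(a) {
    sel <- records$arm == a
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(arm = a, n = 0L, n_dementia = 0L, pct_dementia = 0,
                        n_death = 0L, pct_death = 0, person_years = 0,
                        median_followup = NA_real_, empty_arm = TRUE))
    }
    tt <- records$time[sel]; ee <- records$event[sel]
    data.frame(arm = a, n = n,
               n_dementia = sum(ee == 1),
               pct_dementia = round(100 * sum(ee == 1) / n, 1),
               n_death = sum(ee == 2),
               pct_death = round(100 * sum(ee == 2) / n, 1),
               person_years = sum(tt),
               median_followup = median(tt),
               empty_arm = FALSE)
  })
  cov_rows <- list()
  for (cv in attr(records, "covariate_names") %||% character(0)) {
    x <- records[[cv]]
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      for (a in 0:1) {
        xa <- x[records$arm == a]
        n_miss <- sum(xa == "missing", na.rm = TRUE)
        n_valid <- length(xa) - n_miss
        for (lev in setdiff(levels(x), "missing")) {
          cov_rows[[length(cov_rows) + 1L]] <- data.frame(
            arm = a, covariate = cv, level = lev,
            n = sum(xa == lev, na.rm = TRUE),
            valid_pct = if (n_valid > 0) round(100 * sum(xa == lev, na.rm = TRUE) / n_valid, 1) else NA_real_)
        }
        if (n_miss > 0) {
          cov_rows[[length(cov_rows) + 1L]] <- data.frame(
            arm = a, covariate = cv, level = "missing", n = n_miss,
            valid_pct = NA_real_)
        }
      }
    } else {
      for (a in 0:1) {
        xa <- as.numeric(x[records$arm == a])
        cov_rows[[length(cov_rows) + 1L]] <- data.frame(
          arm = a, covariate = cv, level = "(mean)", n = length(xa),
          valid_pct = round(mean(xa), 1))
      }
    }
  }
  structure(list(events = do.call(rbind, ev_rows),
                 covariates = if (length(cov_rows)) do.call(rbind, cov_rows) else NULL),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (per arm):\n")
  print.data.frame(x$events, row.names = FALSE)
  invisible(x)
}

#' Recompute and check summary-table arithmetic
#'
#' Recomputes every percentage and total of a per-arm event summary
#' from its own raw counts (percentages to one decimal; person-year
#' totals by addition) and flags any mismatch beyond rounding
#' tolerance. Mismatches are findings, not errors.
#'
#' @param events a per-arm data.frame with columns `n`, `n_dementia`,
#'   `pct_dementia`, `n_death`, `pct_death`, `person_years` — either
#'   the `events` element of a [cohort_summary()] or an externally
#'   transcribed table with the same columns.
#' @param tol absolute tolerance on recomputed percentages (default
#'   0.05, i.e. printed one-decimal rounding).
#' @return list of class `consistency_report`: `checked` (the table
#'   with recomputed columns and per-row flags), `total_n`,
#'   `total_person_years`, `n_mismatches`.
#' @export
consistency_report <- function(events, tol = 0.05) {
  if (inherits(events, "cohort_summary")) events <- events$events
  if (is.null(events) || !nrow(events)) {
    return(structure(list(checked = events, total_n = 0,
                          total_person_years = 0, n_mismatches = 0L),
                     class = "consistency_report"))
  }
  chk <- events
  chk$pct_dementia_recomputed <- round(100 * chk$n_dementia / chk$n, 1)
  chk$pct_death_recomputed <- round(100 * chk$n_death / chk$n, 1)
  chk$dementia_pct_ok <- abs(chk$pct_dementia_recomputed - chk$pct_dementia) <= tol
  chk$death_pct_ok <- abs(chk$pct_death_recomputed - chk$pct_death) <= tol
  structure(list(checked = chk,
                 total_n = sum(chk$n),
                 total_person_years = sum(chk$person_years),
                 n_mismatches = sum(!chk$dementia_pct_ok) + sum(!chk$death_pct_ok)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Consistency report: total n = %s, total person-years = %s, mismatches = %d\n",
              format(x$total_n, big.mark = ","),
              format(x$total_person_years, big.mark = ","), x$n_mismatches))
  invisible(x)
}
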