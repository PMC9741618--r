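# Configuration-driven orchestration: cohort -> weights -> fits ->
# curves -> bootstrap -> report bundle, with the sensitivity analyses.

#' Emulation configuration
#'
#' @param covariate_names propensity-model covariates.
#' @param estimand `"ATE"` (primary) or `"ATT"`.
#' @param stabilized stabilize the ATE weights (default TRUE).
#' @param adjust optional covariates for the covariate-adjusted Cox
#'   sensitivity analysis (e.g. `c("age", "sex")`).
#' @param strata optional named list of stratifying covariate names
#'   for subgroup analyses.
#' @param att_sensitivity also run the ATT-weighted analysis.
#' @param B Bayesian bootstrap replications (default 500).
#' @param seed integer seed.
#' @param run_in_years landmark (default 1).
#' @param time_grid_size maximum number of points for reported curves
#'   (default 250; event times are thinned to this size).
#' @return object of class `emulation_config`.
#' @export
emulation_config <- function(covariate_names,
                             estimand = c("ATE", "ATT"),
                             stabilized = TRUE,
                             adjust = NULL,
                             strata = NULL,
                             att_sensitivity = FALSE,
                             B = 500, seed = 1,
                             run_in_years = 1,
                             time_grid_size = 250) {
  estimand <- match.arg(estimand)
  stopifnot(length(covariate_names) >= 1, B >= 1, time_grid_size >= 10)
  structure(list(covariate_names = covariate_names, estimand = estimand,
                 stabilized = stabilized, adjust = adjust, strata = strata,
                 att_sensitivity = att_sensitivity, B = as.integer(B),
                 seed = as.integer(seed), run_in_years = run_in_years,
                 time_grid_size = as.integer(time_grid_size)),
            class = "emulation_config")
}

#' Load an emulation configuration from YAML
#'
#' @param path YAML file with fields matching [emulation_config()].
#' @return an `emulation_config` object.
#' @export
read_emulation_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations", call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(emulation_config, raw)
}

# one full weighted estimation pass; bootstrap weights (if any) are
# multiplied into the propensity likelihood and every estimating
# equation
estimation_pass <- function(records, config, bs_weights = NULL, grid = NULL) {
  pf <- fit_propensity(records, config$covariate_names, base_weights = bs_weights)
  wt <- suppressWarnings(compute_weights(pf, config$estimand, config$stabilized))
  w <- wt$w * (bs_weights %||% rep(1, nrow(records)))
  fit1 <- fit_weighted_cox(records, w, cause = 1)
  fit2 <- fit_weighted_cox(records, w, cause = 2)
  fit_all <- fit_weighted_cox(records, w, cause = "all")
  H01 <- breslow_cumhaz(records, w, fit1)
  H02 <- breslow_cumhaz(records, w, fit2)
  cif0 <- estimate_cif(H01, H02, fit1, fit2, arm = 0)
  cif1 <- estimate_cif(H01, H02, fit1, fit2, arm = 1)
  rd1 <- risk_difference(cif1, cif0, cause = 1)
  rd2 <- risk_difference(cif1, cif0, cause = 2)
  out <- list(propensity = pf, weights = wt,
              fit_dementia = fit1, fit_death = fit2, fit_all_cause = fit_all,
              H01 = H01, H02 = H02, cif_arm0 = cif0, cif_arm1 = cif1,
              rd_dementia = rd1, rd_death = rd2)
  if (!is.null(grid)) {
    out$on_grid <- list(
      hr_dementia = fit1$hr[["arm"]],
      hr_death = fit2$hr[["arm"]],
      hr_all_cause = fit_all$hr[["arm"]],
      cif1_arm0 = cif_at(cif0, 1, grid), cif1_arm1 = cif_at(cif1, 1, grid),
      cif2_arm0 = cif_at(cif0, 2, grid), cif2_arm1 = cif_at(cif1, 2, grid),
      rd_dementia = step_eval(rd1$time, rd1$rd, grid),
      rd_death = step_eval(rd2$time, rd2$rd, grid))
  }
  out
}

#' Run the full target-trial emulation
#'
#' Executes, deterministically given the seed: propensity fit and
#' weighting, covariate balance before/after weighting, the all-cause
#' mortality fit with weighted Kaplan-Meier curves and PH diagnostics,
#' cause-specific Cox fits, plug-in counterfactual CIF and
#' risk-difference curves, nonparametric Aalen-Johansen comparator
#' curves, Bayesian bootstrap bands for all headline estimands, and
#' the requested sensitivity (ATT, covariate-adjusted) and subgroup
#' analyses. Raw EHR tables are first passed through the eligibility
#' builder when supplied instead of prebuilt records.
#'
#' @param config an [emulation_config()].
#' @param records a prebuilt [event_records()] data.frame, or NULL.
#' @param tables an `ehr_tables` object (used when `records` is NULL);
#'   requires `protocol`.
#' @param protocol a [protocol_spec()] for the cohort build.
#' @param out_dir optional directory; when given, curves and tables
#'   are written as CSV and fits as JSON.
#' @return object of class `report_bundle`.
#' @export
run_emulation <- function(config, records = NULL, tables = NULL,
                          protocol = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "emulation_config"))
  attrition <- NULL
  if (is.null(records)) {
    if (is.null(tables) || is.null(protocol))
      stop("either prebuilt records or raw tables plus a protocol are required",
           call. = FALSE)
    built <- apply_eligibility(tables, protocol)
    attrition <- built$attrition
    records <- build_analysis_records(built$cohort, protocol)
    attr(records, "covariate_names") <- intersect(config$covariate_names,
                                                  names(records))
  }
  stopifnot(nrow(records) > 0)

  balance_pre <- standardized_mean_differences(records, config$covariate_names)
  main <- estimation_pass(records, config)
  balance_post <- standardized_mean_differences(records, config$covariate_names,
                                                weights = main$weights)
  km <- weighted_km(records, main$weights)
  aj <- aalen_johansen(records, main$weights)
  ph <- ph_diagnostics(records, main$weights, cause = "all")
  summary_tab <- cohort_summary(records)
  consistency <- consistency_report(summary_tab)

  # reporting grid: event times thinned to the configured size
  all_ev <- sort(unique(records$time[records$event %in% 1:2]))
  grid <- if (length(all_ev) > config$time_grid_size) {
    as.numeric(quantile(all_ev, probs = seq(0, 1, length.out = config$time_grid_size),
                        type = 1, names = FALSE))
  } else all_ev
  grid <- sort(unique(grid))

  boot <- bayesian_bootstrap(
    records,
    pipeline = function(rec, wbs) estimation_pass(rec, config, bs_weights = wbs,
                                                  grid = grid)$on_grid,
    B = config$B, seed = config$seed)

  sensitivity <- list()
  if (config$att_sensitivity && config$estimand == "ATE") {
    att_cfg <- config; att_cfg$estimand <- "ATT"
    sensitivity$att <- estimation_pass(records, att_cfg)
  }
  if (!is.null(config$adjust)) {
    wt <- main$weights
    sensitivity$adjusted <- list(
      fit_dementia = fit_weighted_cox(records, wt, cause = 1, adjust = config$adjust),
      fit_death = fit_weighted_cox(records, wt, cause = 2, adjust = config$adjust),
      fit_all_cause = fit_weighted_cox(records, wt, cause = "all", adjust = config$adjust))
  }
  subgroups <- NULL
  if (!is.null(config$strata)) {
    subgroups <- do.call(rbind, lapply(names(config$strata), function(nm) {
      res <- subgroup_analysis(records, config$strata[[nm]],
                               config$covariate_names,
                               estimand = config$estimand,
                               stabilized = config$stabilized, cause = 1)
      cbind(stratifier = nm, res)
    }))
  }

  bundle <- structure(list(
    attrition = attrition,
    summary = summary_tab,
    consistency = consistency,
    balance_pre = balance_pre,
    balance_post = balance_post,
    main = main,
    km = km,
    aalen_johansen = aj,
    ph_diagnostics = ph,
    grid = grid,
    bootstrap = boot,
    sensitivity = sensitivity,
    subgroups = subgroups,
    meta = list(seed = config$seed, B = config$B,
                estimand = config$estimand,
                n = nrow(records),
                package_version = tryCatch(
                  as.character(utils::packageVersion("emulacomp")),
                  error = function(e) NA_character_))),
    class = "report_bundle")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Target-trial emulation report\n")
  cat(sprintf("  n = %d, estimand = %s, B = %d, seed = %d\n",
              x$meta$n, x$meta$estimand, x$meta$B, x$meta$seed))
  f1 <- x$main$fit_dementia; f2 <- x$main$fit_death; fa <- x$main$fit_all_cause
  b <- x$bootstrap
  cat(sprintf("  HR dementia:  %.3f (95%% CI %.3f-%.3f)\n", f1$hr[["arm"]],
              b$lower$hr_dementia, b$upper$hr_dementia))
  cat(sprintf("  HR death:     %.3f (95%% CI %.3f-%.3f)\n", f2$hr[["arm"]],
              b$lower$hr_death, b$upper$hr_death))
  cat(sprintf("  HR all-cause: %.3f (95%% CI %.3f-%.3f)\n", fa$hr[["arm"]],
              b$lower$hr_all_cause, b$upper$hr_all_cause))
  invisible(x)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, nm) if (!is.null(df))
    write.csv(df, file.path(out_dir, nm), row.names = FALSE)
  wcsv(bundle$attrition, "attrition.csv")
  wcsv(bundle$summary$events, "summary_events.csv")
  wcsv(bundle$balance_pre, "balance_unweighted.csv")
  wcsv(bundle$balance_post, "balance_weighted.csv")
  curves <- do.call(rbind, lapply(c(0, 1), function(a) {
    cv <- if (a == 0) bundle$main$cif_arm0 else bundle$main$cif_arm1
    data.frame(time = cv$time, arm = a, cif_dementia = cv$cif1,
               cif_death = cv$cif2, surv = cv$surv)
  }))
  wcsv(curves, "cif_curves.csv")
  b <- bundle$bootstrap
  rd <- data.frame(time = bundle$grid,
                   rd_dementia = b$point$rd_dementia,
                   rd_dementia_lower = b$lower$rd_dementia,
                   rd_dementia_upper = b$upper$rd_dementia,
                   rd_death = b$point$rd_death,
                   rd_death_lower = b$lower$rd_death,
                   rd_death_upper = b$upper$rd_death)
  wcsv(rd, "risk_difference.csv")
  wcsv(bundle$subgroups, "subgroups.csv")
  fits <- list()
  for (nm in c("fit_dementia", "fit_death", "fit_all_cause")) {
    f <- bundle$main[[nm]]
    key <- sub("^fit_", "", nm)
    fits[[key]] <- list(hr = unname(f$hr[["arm"]]),
                        beta = unname(f$beta[["arm"]]),
                        se_robust = unname(f$se_robust[["arm"]]),
                        wald_p = unname(f$wald_p[["arm"]]),
                        ci_lower = unname(b$lower[[paste0("hr_", key)]]),
                        ci_upper = unname(b$upper[[paste0("hr_", key)]]),
                        n = f$n, n_events = f$n_events)
  }
  fits$meta <- bundle$meta
  fits$ph_diagnostics <- list(
    schoenfeld_global_p = bundle$ph_diagnostics$schoenfeld_global_p,
    logrank_p = bundle$ph_diagnostics$logrank_p)
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
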