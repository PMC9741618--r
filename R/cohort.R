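# Cohort construction under the trial protocol: exposure assignment,
# dementia ascertainment, eligibility filtering with an attrition
# report, and conversion to analysis-ready event records.

#' Assign treatment exposure at baseline
#'
#' Baseline is the date of the first metformin or sulfonylurea
#' prescription inside the study window; the arm is set by that drug
#' (1 metformin, 0 sulfonylurea). The monotherapy flag is FALSE when
#' any other hypoglycemic agent (including insulin) or the opposite
#' index class appears on the baseline date; in the UK dialect it is
#' additionally FALSE when the first 12 months contain a different
#' antidiabetic class or fewer than the required number of index-class
#' prescriptions. Drug names are matched case-insensitively; unknown
#' names pass through as non-antidiabetic.
#'
#' @param prescriptions data.frame with columns `id`, `date`,
#'   `drug_name`.
#' @param spec a [protocol_spec()].
#' @return data.frame with one row per exposed patient: `id`,
#'   `baseline` (Date), `arm`, `monotherapy` (logical).
#' @export
assign_exposure <- function(prescriptions, spec) {
  stopifnot(inherits(spec, "protocol_spec"),
            all(c("id", "date", "drug_name") %in% names(prescriptions)))
  if (!nrow(prescriptions))
    return(data.frame(id = integer(0), baseline = as.Date(character(0)),
                      arm = integer(0), monotherapy = logical(0)))
  rx <- prescriptions
  rx$date <- parse_dates(rx$date, "prescription date")
  dn <- tolower(trimws(rx$drug_name))
  rx$is_met <- dn %in% spec$metformin_names
  rx$is_su <- dn %in% spec$sulfonylurea_names
  rx$is_other <- dn %in% spec$other_antidiabetic_names
  idx <- rx[(rx$is_met | rx$is_su) &
              rx$date >= spec$study_start & rx$date <= spec$study_end, ]
  if (!nrow(idx))
    return(data.frame(id = integer(0), baseline = as.Date(character(0)),
                      arm = integer(0), monotherapy = logical(0)))
  idx <- idx[order(idx$id, idx$date, -idx$is_met), ]
  firsts <- idx[!duplicated(idx$id), ]
  out <- data.frame(id = firsts$id, baseline = firsts$date,
                    arm = as.integer(firsts$is_met))
  mono <- logical(nrow(out))
  rx_by_id <- split(rx, rx$id)
  for (i in seq_len(nrow(out))) {
    pid <- as.character(out$id[i])
    sub <- rx_by_id[[pid]]
    b <- out$baseline[i]; a <- out$arm[i]
    at_base <- sub[sub$date == b, ]
    own <- if (a == 1) at_base$is_met else at_base$is_su
    conflict <- any(at_base$is_other) | any(if (a == 1) at_base$is_su else at_base$is_met)
    ok <- !conflict
    if (ok && spec$dialect == "UK") {
      yr1 <- sub[sub$date >= b & sub$date < b + 365.25, ]
      own_n <- sum(if (a == 1) yr1$is_met else yr1$is_su)
      other <- any(yr1$is_other) | any(if (a == 1) yr1$is_su else yr1$is_met)
      ok <- !other && own_n >= spec$min_monotherapy_prescriptions
    }
    mono[i] <- ok
  }
  out$monotherapy <- mono
  out
}

#' Ascertain dementia onset
#'
#' Onset is the earlier of the first matching dementia diagnosis date
#' and the first dementia-specific drug prescription date; absent when
#' neither exists.
#'
#' @param diagnoses data.frame with `id`, `date`, `code_system`, `code`.
#' @param prescriptions data.frame with `id`, `date`, `drug_name`.
#' @param spec a [protocol_spec()].
#' @return data.frame `id`, `onset` (Date), one row per patient with
#'   an ascertainable onset.
#' @export
ascertain_dementia <- function(diagnoses, prescriptions, spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  cand <- list()
  if (nrow(diagnoses)) {
    dx <- diagnoses
    dx$date <- parse_dates(dx$date, "diagnosis date")
    hit <- code_matches(dx$code_system, dx$code, spec$dementia_codes)
    if (any(hit)) cand$dx <- dx[hit, c("id", "date")]
  }
  if (nrow(prescriptions)) {
    rx <- prescriptions
    rx$date <- parse_dates(rx$date, "prescription date")
    hit <- drug_in(rx$drug_name, spec$dementia_drug_names)
    if (any(hit)) cand$rx <- rx[hit, c("id", "date")]
  }
  if (!length(cand))
    return(data.frame(id = integer(0), onset = as.Date(character(0))))
  all_c <- do.call(rbind, cand)
  agg <- aggregate(date ~ id, data = all_c, FUN = min)
  names(agg) <- c("id", "onset")
  agg[order(agg$id), , drop = FALSE]
}

#' Apply the eligibility protocol and produce an attrition report
#'
#' Exclusion criteria are applied in a fixed, documented order:
#' (1) no index prescription inside the study window, (2) age below
#' the minimum at baseline, (3) insufficient pre-baseline history,
#' (4) prior hypoglycemic exposure (any antidiabetic strictly before
#' baseline), (5) combination therapy at baseline (monotherapy flag),
#' (6) dementia diagnosis or dementia drug before baseline, (7) CKD
#' diagnosis at or before baseline, (8) under `run_in_years` of
#' follow-up with no event, and (9) dementia or death within the
#' washout year. Counts are conserved at every step.
#'
#' @param tables a list (or `ehr_tables` object) with data.frames
#'   `patients` (`id`, `birth_date`, `sex`, `region`, `ses`,
#'   optionally `death_date`), `prescriptions`, `diagnoses`, `labs`.
#' @param spec a [protocol_spec()].
#' @return list with `cohort` (one row per eligible patient, including
#'   baseline, arm, age, onset/death/last-encounter dates) and
#'   `attrition` (class `attrition_report`).
#' @export
apply_eligibility <- function(tables, spec) {
  if (inherits(tables, "ehr_tables")) tables <- tables$tables
  for (nm in c("patients", "prescriptions", "diagnoses", "labs")) {
    if (is.null(tables[[nm]]))
      stop(sprintf("required table '%s' is missing", nm), call. = FALSE)
  }
  pat <- tables$patients
  rx <- tables$prescriptions
  if (nrow(rx)) rx$date <- parse_dates(rx$date, "prescription date")
  steps <- list()
  n_total <- nrow(pat)

  if (n_total == 0L) {
    att <- attrition_report(data.frame(
      criterion = "no index prescription in study window",
      n_excluded = 0L, n_remaining = 0L))
    return(list(cohort = pat[0, , drop = FALSE], attrition = att))
  }

  exposure <- assign_exposure(tables$prescriptions, spec)
  onsets <- ascertain_dementia(tables$diagnoses, tables$prescriptions, spec)

  coh <- merge(pat, exposure, by = "id", all.x = TRUE)
  coh$birth_date <- parse_dates(coh$birth_date, "birth date")
  if (!"death_date" %in% names(coh)) coh$death_date <- NA
  coh$death_date <- as.Date(as.character(coh$death_date), format = "%Y-%m-%d")
  coh <- merge(coh, onsets, by = "id", all.x = TRUE)

  # earliest and latest record date per patient across all tables
  dates_of <- function(tab, col = "date") {
    if (is.null(tab) || !nrow(tab)) return(NULL)
    data.frame(id = tab$id, date = parse_dates(tab[[col]], "record date"))
  }
  all_dates <- do.call(rbind, c(
    list(dates_of(tables$prescriptions), dates_of(tables$diagnoses),
         dates_of(tables$labs))))
  first_rec <- aggregate(date ~ id, all_dates, min); names(first_rec) <- c("id", "first_record")
  last_rec <- aggregate(date ~ id, all_dates, max); names(last_rec) <- c("id", "last_encounter")
  coh <- merge(merge(coh, first_rec, by = "id", all.x = TRUE),
               last_rec, by = "id", all.x = TRUE)

  drop_step <- function(coh, keep, label) {
    steps[[length(steps) + 1L]] <<- data.frame(
      criterion = label, n_excluded = sum(!keep), n_remaining = sum(keep))
    coh[keep, , drop = FALSE]
  }

  coh <- drop_step(coh, !is.na(coh$baseline),
                   "no index prescription in study window")
  coh$age <- age_at(coh$birth_date, coh$baseline)
  coh <- drop_step(coh, coh$age >= spec$min_age,
                   sprintf("age < %d at baseline", spec$min_age))
  coh <- drop_step(coh, !is.na(coh$first_record) &
                     years_between(coh$first_record, coh$baseline) >= spec$history_years,
                   sprintf("under %g years of pre-baseline history", spec$history_years))
  # prior hypoglycemic exposure: any antidiabetic strictly before baseline
  dn <- tolower(trimws(rx$drug_name))
  anti <- rx[dn %in% c(spec$metformin_names, spec$sulfonylurea_names,
                       spec$other_antidiabetic_names), ]
  prior_ids <- unique(anti$id[which(anti$date < coh$baseline[match(anti$id, coh$id)])])
  coh <- drop_step(coh, !(coh$id %in% prior_ids), "prior hypoglycemic exposure")
  coh <- drop_step(coh, coh$monotherapy, "combination therapy at baseline")
  coh <- drop_step(coh, is.na(coh$onset) | coh$onset >= coh$baseline,
                   "dementia or dementia drug before baseline")
  # CKD at treatment initiation
  ckd_ids <- integer(0)
  if (nrow(tables$diagnoses)) {
    dx <- tables$diagnoses
    dx$date <- parse_dates(dx$date, "diagnosis date")
    ckd <- dx[code_matches(dx$code_system, dx$code, spec$ckd_codes), ]
    ckd_ids <- unique(ckd$id[which(ckd$date <= coh$baseline[match(ckd$id, coh$id)])])
  }
  coh <- drop_step(coh, !(coh$id %in% ckd_ids), "CKD at baseline")

  # follow-up and washout
  event_years <- function(coh) {
    ev <- suppressWarnings(pmin(coh$onset, coh$death_date, na.rm = TRUE))
    years_between(coh$baseline, ev)
  }
  yrs_event <- event_years(coh)
  yrs_last <- years_between(coh$baseline, pmin(coh$last_encounter, spec$study_end))
  early_event <- !is.na(yrs_event) & yrs_event <= spec$run_in_years
  coh <- drop_step(coh, early_event | yrs_last >= spec$run_in_years,
                   sprintf("under %g years of follow-up", spec$run_in_years))
  yrs_event <- event_years(coh)
  coh <- drop_step(coh, is.na(yrs_event) | yrs_event > spec$run_in_years,
                   "dementia or death within the washout year")

  rownames(coh) <- NULL
  list(cohort = coh, attrition = attrition_report(do.call(rbind, steps),
                                                  n_input = n_total))
}

#' Attrition (consort) report
#'
#' @param steps data.frame with `criterion`, `n_excluded`,
#'   `n_remaining` in application order.
#' @param n_input number of patients entering the filter chain.
#' @return data.frame of class `attrition_report`.
#' @export
attrition_report <- function(steps, n_input = NULL) {
  stopifnot(all(c("criterion", "n_excluded", "n_remaining") %in% names(steps)))
  if (any(diff(steps$n_remaining) > 0))
    stop("remaining counts must be nonincreasing", call. = FALSE)
  structure(steps, n_input = n_input,
            class = c("attrition_report", "data.frame"))
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("Attrition report",
      if (!is.null(attr(x, "n_input"))) sprintf(" (input n = %d)", attr(x, "n_input")),
      ":\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Build analysis-ready event records from an eligible cohort
#'
#' Follow-up time T runs from baseline to the earliest of dementia
#' onset, death, last encounter, and the study end; E is 1 when
#' dementia comes first, 2 for death without prior dementia, 0
#' otherwise. A dementia record dated after death is an integrity
#' error. The time origin remains baseline; downstream risk sets begin
#' at the run-in landmark.
#'
#' @param cohort the `cohort` data.frame from [apply_eligibility()].
#' @param spec a [protocol_spec()].
#' @param covariate_names patient columns carried along as analysis
#'   covariates.
#' @return an [event_records()] data.frame.
#' @export
build_analysis_records <- function(cohort, spec,
                                   covariate_names = intersect(c("sex", "region", "ses", "age"),
                                                               names(cohort))) {
  stopifnot(inherits(spec, "protocol_spec"), nrow(cohort) > 0)
  bad <- !is.na(cohort$onset) & !is.na(cohort$death_date) &
    cohort$onset > cohort$death_date
  if (any(bad))
    stop(sprintf("dementia recorded after death for id(s): %s",
                 paste(head(cohort$id[bad], 10L), collapse = ", ")), call. = FALSE)
  exit <- pmin(cohort$onset, cohort$death_date,
               pmin(cohort$last_encounter, spec$study_end), spec$study_end,
               na.rm = TRUE)
  time <- years_between(cohort$baseline, exit)
  event <- ifelse(!is.na(cohort$onset) & cohort$onset == exit, 1L,
                  ifelse(!is.na(cohort$death_date) & cohort$death_date == exit, 2L, 0L))
  keep <- !(event %in% 1:2 & time <= spec$run_in_years)
  df <- data.frame(id = cohort$id, time = time, event = event, arm = cohort$arm)
  for (cv in covariate_names) df[[cv]] <- cohort[[cv]]
  df <- df[keep & df$time > 0, , drop = FALSE]
  rownames(df) <- NULL
  event_records(df, covariate_names = covariate_names)
}
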