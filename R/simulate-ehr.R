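# Raw EHR-style table generator with planted protocol violations.
#
# The fixture emits patients / prescriptions / diagnoses / labs tables
# for which the cohort builder's attrition is fixed by construction:
# every "clean" subject passes all eligibility criteria, and each
# planted violator fails exactly one criterion. Outcome dynamics are
# deliberately simple (constant hazards, no covariate effects): the
# fixture's purpose is protocol logic, not disease realism.

violation_types <- c("under_age", "short_history", "prior_hypoglycemic",
                     "combination_therapy", "baseline_dementia",
                     "dementia_drug_before_baseline", "baseline_ckd",
                     "short_followup", "event_in_run_in")

#' Simulate raw EHR tables with planted protocol violations
#'
#' @param params a [sim_params()] object; `n_subjects`, the baseline
#'   hazard rates (first segment) and the censoring model drive the
#'   outcome draw.
#' @param violations named integer vector of violators to plant;
#'   allowed names: `r paste0('\x60', violation_types, '\x60', collapse = ", ")`.
#'   Each violator fails exactly that one criterion.
#' @param seed integer seed.
#' @param spec a [protocol_spec()] supplying the study window and drug
#'   and code vocabularies (default [protocol_spec()]).
#' @return object of class `ehr_tables`: list with `tables` (patients,
#'   prescriptions, diagnoses, labs) and `truth` (planted violation
#'   counts, the expected per-criterion attrition in the builder's
#'   order, and the expected final cohort size).
#' @export
simulate_ehr_tables <- function(params, violations = integer(0), seed,
                                spec = protocol_spec()) {
  stopifnot(inherits(params, "sim_params"), inherits(spec, "protocol_spec"))
  violations <- violations[violations > 0]
  if (length(violations)) {
    stopifnot(!is.null(names(violations)),
              all(names(violations) %in% violation_types))
  }
  n <- params$n_subjects
  if (sum(violations) > n)
    stop("planted violation counts exceed n_subjects", call. = FALSE)
  set.seed(as.integer(seed))

  run_in <- spec$run_in_years
  h1 <- params$hazards$dementia$base[1L]
  h2 <- params$hazards$death$base[1L]
  cen_rate <- params$censoring$rate

  id <- seq_len(n)
  # baseline leaves >= history + 0.3 years of lead-in and >= 1.5 years
  # of potential follow-up inside the window
  lead <- spec$history_years + 0.3
  span <- as.numeric(spec$study_end - spec$study_start) / days_per_year
  baseline <- spec$study_start +
    round(runif(n, lead, span - 1.5) * days_per_year)
  age <- 55L + sample.int(30L, n, replace = TRUE) - 1L
  birth_date <- baseline - round((age + 0.5) * days_per_year)
  arm <- rbinom(n, 1L, 0.6)
  index_drug <- ifelse(arm == 1, "Metformin",
                       sample(c("Glipizide", "Gliclazide"), n, replace = TRUE))

  # event-free through the washout by construction for everyone;
  # violations override below
  t_event <- run_in + 0.05 + rexp(n, max(h1 + h2, 1e-12))
  cause <- ifelse(runif(n) <= h1 / max(h1 + h2, 1e-12), 1L, 2L)
  t_cens <- run_in + 0.05 + if (cen_rate > 0) rexp(n, cen_rate) else Inf
  t_window <- as.numeric(spec$study_end - baseline) / days_per_year
  t_exit <- pmin(t_event, t_cens, t_window)
  event <- ifelse(t_event <= pmin(t_cens, t_window), cause, 0L)

  history_date <- baseline - round((spec$history_years + 0.3) * days_per_year)
  death_date <- as.Date(ifelse(event == 2, baseline + round(t_exit * days_per_year), NA),
                        origin = "1970-01-01")
  onset_date <- as.Date(ifelse(event == 1, baseline + round(t_exit * days_per_year), NA),
                        origin = "1970-01-01")
  exit_date <- baseline + round(t_exit * days_per_year)

  # plant violations, one criterion per violator, on the first slots
  planted <- rep(NA_character_, n)
  slot <- 1L
  for (vt in names(violations)) {
    k <- violations[[vt]]
    idx <- slot:(slot + k - 1L)
    planted[idx] <- vt
    slot <- slot + k
  }
  for (i in which(!is.na(planted))) {
    switch(planted[i],
      under_age = {
        age[i] <- spec$min_age - 5L
        birth_date[i] <- baseline[i] - round((age[i] + 0.5) * days_per_year)
      },
      short_history = {
        history_date[i] <- baseline[i] - round(0.3 * days_per_year)
      },
      combination_therapy = {
        arm[i] <- 1L; index_drug[i] <- "Metformin"
      },
      event_in_run_in = {
        event[i] <- 2L
        exit_date[i] <- baseline[i] + round(0.5 * days_per_year)
        death_date[i] <- exit_date[i]; onset_date[i] <- NA
      },
      short_followup = {
        event[i] <- 0L
        exit_date[i] <- baseline[i] + round(0.5 * days_per_year)
        death_date[i] <- NA; onset_date[i] <- NA
      },
      {})
  }

  patients <- data.frame(
    id = id,
    birth_date = birth_date,
    sex = sample(c("F", "M"), n, replace = TRUE),
    region = sample(paste0("region_", 1:4), n, replace = TRUE),
    ses = sample(c("low", "middle", "high"), n, replace = TRUE,
                 prob = c(0.2, 0.5, 0.3)),
    death_date = death_date)

  rx <- list(data.frame(id = id, date = baseline, drug_name = index_drug),
             data.frame(id = id, date = baseline + 60, drug_name = index_drug),
             data.frame(id = id, date = baseline + 150, drug_name = index_drug))
  dx <- list()
  labs <- list(
    data.frame(id = id, date = history_date, test_name = "HbA1C",
               value = round(rnorm(n, 7.5, 1), 1)),
    data.frame(id = id, date = exit_date, test_name = "HbA1C",
               value = round(rnorm(n, 7.2, 1), 1)))

  has_onset <- !is.na(onset_date)
  if (any(has_onset)) {
    dx[[length(dx) + 1L]] <- data.frame(
      id = id[has_onset], date = onset_date[has_onset],
      code_system = "ICD10", code = "F03")
  }
  for (i in which(!is.na(planted))) {
    switch(planted[i],
      prior_hypoglycemic = {
        rx[[length(rx) + 1L]] <- data.frame(
          id = id[i], date = baseline[i] - round(2 * days_per_year),
          drug_name = "Insulin")
      },
      combination_therapy = {
        rx[[length(rx) + 1L]] <- data.frame(
          id = id[i], date = baseline[i], drug_name = "Glipizide")
      },
      baseline_dementia = {
        dx[[length(dx) + 1L]] <- data.frame(
          id = id[i], date = baseline[i] - round(0.5 * days_per_year),
          code_system = "ICD10", code = "F03")
      },
      dementia_drug_before_baseline = {
        rx[[length(rx) + 1L]] <- data.frame(
          id = id[i], date = baseline[i] - round(0.4 * days_per_year),
          drug_name = "Donepezil")
      },
      baseline_ckd = {
        dx[[length(dx) + 1L]] <- data.frame(
          id = id[i], date = baseline[i] - round(0.5 * days_per_year),
          code_system = "ICD10", code = "N18.3")
      },
      {})
  }

  fmt <- function(tabs) {
    out <- do.call(rbind, tabs)
    out <- out[order(out$id, out$date), , drop = FALSE]
    out$date <- format(as.Date(out$date), "%Y-%m-%d")
    rownames(out) <- NULL
    out
  }
  prescriptions <- fmt(rx)
  diagnoses <- if (length(dx)) fmt(dx) else
    data.frame(id = integer(0), date = character(0),
               code_system = character(0), code = character(0))
  labs <- fmt(labs)
  patients$birth_date <- format(patients$birth_date, "%Y-%m-%d")
  patients$death_date <- ifelse(is.na(patients$death_date), NA,
                                format(patients$death_date, "%Y-%m-%d"))

  get0v <- function(nm) if (nm %in% names(violations)) violations[[nm]] else 0L
  expected_attrition <- data.frame(
    criterion = c("no index prescription in study window",
                  sprintf("age < %d at baseline", spec$min_age),
                  sprintf("under %g years of pre-baseline history", spec$history_years),
                  "prior hypoglycemic exposure",
                  "combination therapy at baseline",
                  "dementia or dementia drug before baseline",
                  "CKD at baseline",
                  sprintf("under %g years of follow-up", spec$run_in_years),
                  "dementia or death within the washout year"),
    n_excluded = c(0L, get0v("under_age"), get0v("short_history"),
                   get0v("prior_hypoglycemic"), get0v("combination_therapy"),
                   get0v("baseline_dementia") + get0v("dementia_drug_before_baseline"),
                   get0v("baseline_ckd"), get0v("short_followup"),
                   get0v("event_in_run_in")))

  structure(list(
    tables = list(patients = patients, prescriptions = prescriptions,
                  diagnoses = diagnoses, labs = labs),
    truth = list(violations = as.list(violations),
                 expected_attrition = expected_attrition,
                 expected_cohort_size = n - sum(violations))),
    class = "ehr_tables")
}

#' @export
print.ehr_tables <- function(x, ...) {
  cat(sprintf("Raw EHR tables: %d patients, %d prescriptions, %d diagnoses, %d labs; expected cohort %d\n",
              nrow(x$tables$patients), nrow(x$tables$prescriptions),
              nrow(x$tables$diagnoses), nrow(x$tables$labs),
              x$truth$expected_cohort_size))
  invisible(x)
}

#' Write EHR tables to CSV with a JSON truth sidecar
#'
#' @param x an `ehr_tables` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_ehr_tables <- function(x, dir) {
  stopifnot(inherits(x, "ehr_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(x$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(x$tables[[nm]], p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(x$truth, tp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, tp))
}

#' Read EHR tables written by [write_ehr_tables()]
#'
#' @param dir directory containing the four CSV tables.
#' @return an `ehr_tables` object (truth sidecar attached when present).
#' @export
read_ehr_tables <- function(dir) {
  tabs <- lapply(c(patients = "patients", prescriptions = "prescriptions",
                   diagnoses = "diagnoses", labs = "labs"), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) stop(sprintf("required table '%s' is missing", nm), call. = FALSE)
    utils::read.csv(p, stringsAsFactors = FALSE,
                    colClasses = c(id = "integer"))
  })
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  structure(list(tables = tabs, truth = truth), class = "ehr_tables")
}
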