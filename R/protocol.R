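# Trial-protocol specification for the cohort builder.

default_metformin_names <- c("metformin", "glucophage", "glumetza", "fortamet")

default_sulfonylurea_names <- c(
  # first generation
  "tolbutamide", "chlorpropamide", "tolazamide", "acetohexamide",
  # second generation
  "gliclazide", "glibenclamide", "glyburide", "glipizide", "glimepiride",
  "gliquidone", "glibornuride", "glymidine sodium")

default_other_antidiabetic_names <- c(
  "insulin", "insulin glargine", "insulin aspart", "insulin lispro",
  "sitagliptin", "saxagliptin", "linagliptin", "vildagliptin",
  "pioglitazone", "rosiglitazone",
  "exenatide", "liraglutide", "dulaglutide",
  "dapagliflozin", "canagliflozin", "empagliflozin",
  "acarbose", "miglitol", "nateglinide", "repaglinide")

default_dementia_drug_names <- c(
  "donepezil", "galantamine", "rivastigmine", "memantine",
  "aricept", "razadyne", "exelon", "namenda")

# diagnosis codes are matched by prefix within their code system
default_dementia_codes <- data.frame(
  code_system = c(rep("ICD9", 3), rep("ICD10", 6)),
  code = c("290", "294.1", "331",
           "F00", "F01", "F02", "F03", "G30", "G31"),
  stringsAsFactors = FALSE)

default_ckd_codes <- data.frame(
  code_system = c("ICD9", "ICD10"),
  code = c("585", "N18"),
  stringsAsFactors = FALSE)

#' Trial-protocol specification
#'
#' Encodes the eligibility and exposure rules of the emulated trial:
#' study window, minimum age at baseline (inclusive), minimum
#' pre-baseline history, the run-in washout, the drug-name lists, the
#' diagnosis-code lists (matched case-insensitively by prefix within
#' a code system), and the monotherapy dialect. The `"US"` dialect
#' requires a single index prescription and flags combination therapy
#' on the baseline date; the `"UK"` dialect additionally requires at
#' least `min_monotherapy_prescriptions` index-class prescriptions and
#' no other antidiabetic class during the first 12 months.
#'
#' @param min_age minimum age at baseline in completed years (default 50).
#' @param run_in_years washout duration (default 1).
#' @param history_years minimum pre-baseline registration (default 1).
#' @param study_start,study_end study window dates.
#' @param metformin_names,sulfonylurea_names,other_antidiabetic_names,dementia_drug_names
#'   drug-name lists, matched case-insensitively.
#' @param dementia_codes,ckd_codes data.frames with `code_system`,
#'   `code` columns (prefix match).
#' @param dialect `"US"` or `"UK"`.
#' @param min_monotherapy_prescriptions minimum index-class
#'   prescriptions in the first 12 months (UK dialect; default 2).
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(min_age = 50,
                          run_in_years = 1,
                          history_years = 1,
                          study_start = "2007-01-01",
                          study_end = "2017-09-30",
                          metformin_names = default_metformin_names,
                          sulfonylurea_names = default_sulfonylurea_names,
                          other_antidiabetic_names = default_other_antidiabetic_names,
                          dementia_drug_names = default_dementia_drug_names,
                          dementia_codes = default_dementia_codes,
                          ckd_codes = default_ckd_codes,
                          dialect = c("US", "UK"),
                          min_monotherapy_prescriptions = 2) {
  dialect <- match.arg(dialect)
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  stopifnot(study_start < study_end,
            length(metformin_names) > 0, length(sulfonylurea_names) > 0,
            nrow(dementia_codes) > 0, nrow(ckd_codes) > 0,
            min_age >= 0, run_in_years >= 0, history_years >= 0)
  structure(list(min_age = min_age,
                 run_in_years = run_in_years,
                 history_years = history_years,
                 study_start = study_start,
                 study_end = study_end,
                 metformin_names = tolower(metformin_names),
                 sulfonylurea_names = tolower(sulfonylurea_names),
                 other_antidiabetic_names = tolower(other_antidiabetic_names),
                 dementia_drug_names = tolower(dementia_drug_names),
                 dementia_codes = dementia_codes,
                 ckd_codes = ckd_codes,
                 dialect = dialect,
                 min_monotherapy_prescriptions =
                   if (dialect == "US") 1L else as.integer(min_monotherapy_prescriptions)),
            class = "protocol_spec")
}

# case-insensitive membership in a drug-name list
drug_in <- function(drug_name, name_list) tolower(trimws(drug_name)) %in% name_list

# prefix match of codes within code systems
code_matches <- function(code_system, code, code_list) {
  hit <- rep(FALSE, length(code))
  cs <- toupper(trimws(code_system)); cd <- toupper(trimws(code))
  for (i in seq_len(nrow(code_list))) {
    sel <- cs == toupper(code_list$code_system[i]) &
      startsWith(cd, toupper(code_list$code[i]))
    hit <- hit | sel
  }
  hit
}
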