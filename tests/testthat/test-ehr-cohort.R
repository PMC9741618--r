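# Cohort builder: exposure assignment, outcome ascertainment,
# eligibility filtering with exact attrition, and record construction.

spec_us <- protocol_spec()
spec_uk <- protocol_spec(study_start = "2001-01-01", study_end = "2017-05-31",
                         dialect = "UK", min_monotherapy_prescriptions = 2)

test_that("exposure assignment sets arm and baseline from the first index prescription", {
  rx <- data.frame(id = c(1, 1, 2),
                   date = c("2010-05-01", "2011-02-01", "2012-03-15"),
                   drug_name = c("Metformin", "Metformin", "GLIPIZIDE"))
  ex <- assign_exposure(rx, spec_us)
  expect_equal(ex$arm[ex$id == 1], 1L)
  expect_equal(ex$baseline[ex$id == 1], as.Date("2010-05-01"))
  expect_true(all(ex$monotherapy))
  # case-insensitive sulfonylurea match
  expect_equal(ex$arm[ex$id == 2], 0L)
})

test_that("combination therapy on the baseline date clears the monotherapy flag", {
  rx <- data.frame(id = c(1, 1), date = c("2010-05-01", "2010-05-01"),
                   drug_name = c("Metformin", "Glipizide"))
  ex <- assign_exposure(rx, spec_us)
  expect_false(ex$monotherapy)
  # unknown drug names pass through as non-antidiabetic
  rx2 <- data.frame(id = 1, date = c("2010-05-01", "2010-05-01"),
                    drug_name = c("Metformin", "Lisinopril"))
  expect_true(assign_exposure(rx2, spec_us)$monotherapy)
})

test_that("UK dialect requires two consistent prescriptions in the first year", {
  rx1 <- data.frame(id = 1, date = "2010-05-01", drug_name = "Gliclazide")
  expect_false(assign_exposure(rx1, spec_uk)$monotherapy)
  rx2 <- data.frame(id = 1, date = c("2010-05-01", "2010-09-01"),
                    drug_name = c("Gliclazide", "Gliclazide"))
  expect_true(assign_exposure(rx2, spec_uk)$monotherapy)
  # a different antidiabetic class inside the year breaks monotherapy
  rx3 <- rbind(rx2, data.frame(id = 1, date = "2010-12-01", drug_name = "Insulin"))
  expect_false(assign_exposure(rx3, spec_uk)$monotherapy)
})

test_that("unparseable prescription dates are reported with their rows", {
  rx <- data.frame(id = 1:2, date = c("2010-05-01", "not-a-date"),
                   drug_name = c("Metformin", "Metformin"))
  expect_error(assign_exposure(rx, spec_us), "unparseable.*2")
})

test_that("dementia onset is the earlier of diagnosis and dementia drug", {
  dx <- data.frame(id = 1, date = "2015-03-01", code_system = "ICD10", code = "F03")
  rx <- data.frame(id = 1, date = "2014-06-01", drug_name = "Donepezil")
  on <- ascertain_dementia(dx, rx, spec_us)
  expect_equal(on$onset, as.Date("2014-06-01"))
  none <- ascertain_dementia(dx[0, ], rx[0, ], spec_us)
  expect_equal(nrow(none), 0L)
  # code prefixes match within their system only
  dx9 <- data.frame(id = 2, date = "2015-01-01", code_system = "ICD9", code = "290.41")
  expect_equal(nrow(ascertain_dementia(dx9, rx[0, ], spec_us)), 1L)
  dx_wrong <- data.frame(id = 3, date = "2015-01-01", code_system = "ICD10", code = "290.41")
  expect_equal(nrow(ascertain_dementia(dx_wrong, rx[0, ], spec_us)), 0L)
})

test_that("planted violations reproduce their attrition counts exactly", {
  p <- default_sim_params(100)
  v <- c(under_age = 3, prior_hypoglycemic = 2, baseline_dementia = 1)
  tabs <- simulate_ehr_tables(p, v, seed = 21)
  res <- apply_eligibility(tabs, spec_us)
  expect_equal(res$attrition$n_excluded, tabs$truth$expected_attrition$n_excluded)
  expect_equal(nrow(res$cohort), 94L)
  # count conservation at every step
  n_in <- c(100L, head(res$attrition$n_remaining, -1L))
  expect_equal(res$attrition$n_excluded + res$attrition$n_remaining, n_in)
})

test_that("zero planted violations retain every subject; seeds reproduce tables", {
  p <- default_sim_params(60)
  tabs <- simulate_ehr_tables(p, integer(0), seed = 3)
  res <- apply_eligibility(tabs, spec_us)
  expect_equal(nrow(res$cohort), 60L)
  expect_equal(sum(res$attrition$n_excluded), 0L)
  tabs2 <- simulate_ehr_tables(p, integer(0), seed = 3)
  expect_identical(tabs$tables, tabs2$tables)
  expect_error(simulate_ehr_tables(p, c(under_age = 61), seed = 1), "exceed")
})

test_that("empty patients table yields an empty cohort and an all-zero report", {
  empty <- list(patients = data.frame(id = integer(0), birth_date = character(0),
                                      sex = character(0), region = character(0),
                                      ses = character(0)),
                prescriptions = data.frame(id = integer(0), date = character(0),
                                           drug_name = character(0)),
                diagnoses = data.frame(id = integer(0), date = character(0),
                                       code_system = character(0), code = character(0)),
                labs = data.frame(id = integer(0), date = character(0),
                                  test_name = character(0), value = numeric(0)))
  res <- apply_eligibility(empty, spec_us)
  expect_equal(nrow(res$cohort), 0L)
  expect_true(all(res$attrition$n_excluded == 0))
  expect_error(apply_eligibility(empty[-1], spec_us), "patients")
})

test_that("age exactly at the minimum is retained (inclusive threshold)", {
  p <- default_sim_params(5)
  tabs <- simulate_ehr_tables(p, integer(0), seed = 9)
  pat <- tabs$tables$patients
  rx <- tabs$tables$prescriptions
  b <- as.Date(rx$date[rx$id == 1][1])
  # exactly 50 completed years at baseline
  pat$birth_date[pat$id == 1] <- format(b - round(50.5 * 365.25), "%Y-%m-%d")
  tabs$tables$patients <- pat
  res <- apply_eligibility(tabs, spec_us)
  expect_true(1 %in% res$cohort$id)
  expect_equal(res$cohort$age[res$cohort$id == 1], 50)
})

test_that("analysis records implement first-event semantics and the washout", {
  coh <- data.frame(
    id = 1:4,
    baseline = as.Date("2008-01-01"),
    arm = c(1L, 0L, 1L, 0L),
    age = 60,
    onset = as.Date(c("2011-01-01", NA, NA, NA)),            # dementia at 3.0y
    death_date = as.Date(c("2013-01-01", "2008-07-01", NA, NA)), # death 5y; 0.5y
    last_encounter = as.Date(c("2013-01-01", "2008-07-01", "2017-09-30", "2012-01-01")))
  rec <- build_analysis_records(coh, spec_us, covariate_names = "age")
  expect_equal(nrow(rec), 3L)  # washout removes id 2
  r1 <- rec[rec$id == 1, ]
  expect_equal(r1$event, 1L)
  expect_equal(r1$time, 3.0, tolerance = 0.01)
  r3 <- rec[rec$id == 3, ]                                   # censored at study end
  expect_equal(r3$event, 0L)
  expect_equal(r3$time,
               as.numeric(spec_us$study_end - as.Date("2008-01-01")) / 365.25,
               tolerance = 1e-9)
  # integrity: dementia recorded after death
  bad <- coh[1, ]; bad$onset <- as.Date("2014-01-01")
  expect_error(build_analysis_records(bad, spec_us, covariate_names = "age"),
               "after death")
})

test_that("cohort summary arithmetic is internally consistent and person-years add", {
  p <- default_sim_params(3000)
  r <- simulate_cohort(p, 12)
  s <- cohort_summary(r)
  cr <- consistency_report(s)
  expect_equal(cr$n_mismatches, 0L)
  expect_equal(cr$total_person_years, sum(r$time))
  expect_equal(s$events$person_years[1] + s$events$person_years[2], sum(r$time))
  # single censored subject: zero events, person-years = T
  one <- make_records(time = 4.2, event = 0L, arm = 1L)
  s1 <- cohort_summary(one)
  expect_equal(s1$events$n_dementia[2], 0L)
  expect_equal(s1$events$person_years[2], 4.2)
  expect_true(s1$events$empty_arm[1])
})

test_that("summary checker reproduces published-style percentages and totals", {
  # a transcribed two-arm mortality summary: counts and printed values
  printed <- data.frame(
    arm = c(1, 0), n = c(11229, 1962),
    n_dementia = c(869, 241), pct_dementia = c(7.7, 12.3),
    n_death = c(415, 154), pct_death = c(3.7, 7.8),
    person_years = c(63060, 11047))
  cr <- consistency_report(printed)
  expect_equal(cr$n_mismatches, 0L)
  expect_equal(cr$checked$pct_death_recomputed, c(3.7, 7.8))
  expect_equal(cr$checked$pct_dementia_recomputed, c(7.7, 12.3))
  expect_equal(cr$total_person_years, 74107)
  expect_equal(cr$total_n, 13191)
  # and the UK-style cohort total
  expect_equal(94208 + 13817, 108025)
  empty <- consistency_report(printed[0, ])
  expect_equal(empty$n_mismatches, 0L)
})
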