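# Hand-built single-person scenarios exercising each rule of the case
# definition, then property tests against the brute-force oracle.

claims_one_woman <- function(outpatient = NULL, inpatient = NULL,
                             procedures = NULL, death = NA) {
  make_claims(persons = person_row("P1", death_date = death),
              outpatient = outpatient, inpatient = inpatient,
              procedures = procedures)
}

run_one <- function(claims, site, spec) {
  identify_incident_cases(claims, cohort_of(claims), site, spec)
}

test_that("only certain/main-discharge diagnoses can open an index", {
  # a suspected diagnosis earlier in the year does not index; the first
  # certain one does
  cl <- make_claims(
    persons = person_row("P1", sex = "M"),
    outpatient = dplyr::bind_rows(
      out_dx("P1", "2013Q1", icd = "C61", certainty = "V"),
      out_dx("P1", "2013Q3", icd = "C61", certainty = "G"),
      out_dx("P1", "2013Q4", icd = "C61", certainty = "G")
    )
  )
  idx <- find_index_quarter(cl, "PROSTATE")
  expect_equal(idx$index_quarter, "2013Q3")

  # main-discharge inpatient in Q1 beats a later outpatient G
  cl2 <- claims_one_woman(
    outpatient = out_dx("P1", "2013Q3"),
    inpatient = inp_dx("P1", "2013-02-10", icd = "C18.0")
  )
  idx2 <- find_index_quarter(cl2, "COLORECTAL")
  expect_equal(idx2$index_quarter, "2013Q1")
  expect_equal(idx2$index_setting, "INPATIENT")

  # an ancillary inpatient diagnosis alone never opens an index
  cl3 <- claims_one_woman(
    inpatient = inp_dx("P1", "2013-02-10", dx_type = "ANCILLARY")
  )
  expect_equal(nrow(find_index_quarter(cl3, "BREAST")), 0)
})

test_that("status-post and ancillary diagnoses count in the lookback", {
  base <- out_dx("P1", "2013Q2")
  idx <- tibble::tibble(person_id = "P1",
                        index_qi = parse_quarter("2013Q2"))

  # Z two quarters before the index, lookback 1 year
  cl <- claims_one_woman(outpatient = dplyr::bind_rows(
    base, out_dx("P1", "2012Q4", certainty = "Z")
  ))
  expect_false(passes_lookback(cl, "BREAST", idx, 1)$passes_lookback)

  # ancillary inpatient 7 quarters before: invisible to L1, fatal for L2
  cl2 <- make_claims(
    persons = person_row("P1"),
    outpatient = out_dx("P1", "2013Q2", icd = "C20"),
    inpatient = inp_dx("P1", "2011-08-20", icd = "C20",
                       dx_type = "ANCILLARY")
  )
  expect_true(passes_lookback(cl2, "COLORECTAL", idx, 1)$passes_lookback)
  expect_false(passes_lookback(cl2, "COLORECTAL", idx, 2)$passes_lookback)

  # V-coded diagnoses are ignored everywhere, including the lookback
  cl3 <- claims_one_woman(outpatient = dplyr::bind_rows(
    base, out_dx("P1", "2012Q4", certainty = "V")
  ))
  expect_true(passes_lookback(cl3, "BREAST", idx, 7)$passes_lookback)
})

test_that("confirmation windows and event kinds follow the algorithm spec", {
  # status post in the next quarter confirms a C1 algorithm
  cl <- claims_one_woman(outpatient = dplyr::bind_rows(
    out_dx("P1", "2013Q2"), out_dx("P1", "2013Q3", certainty = "Z")
  ))
  res <- run_one(cl, "BREAST", "L1-C1")
  expect_equal(res$confirm_kind, "SECOND_DIAGNOSIS")

  # the index record never confirms itself: a lone diagnosis fails C1
  cl_lone <- claims_one_woman(outpatient = out_dx("P1", "2013Q2"))
  expect_equal(nrow(run_one(cl_lone, "BREAST", "L1-C1")), 0)
  expect_equal(run_one(cl_lone, "BREAST", "L1-C0")$confirm_kind,
               "NONE_REQUIRED")

  # a second diagnosis in the index quarter itself does not confirm
  cl_same_q <- claims_one_woman(
    outpatient = out_dx("P1", "2013Q2"),
    inpatient = inp_dx("P1", "2013-05-20")
  )
  expect_equal(nrow(run_one(cl_same_q, "BREAST", "L1-C1")), 0)

  # death in the index quarter is an admissible confirmatory event...
  cl_death <- claims_one_woman(outpatient = out_dx("P1", "2013Q2"),
                               death = "2013-06-01")
  expect_equal(run_one(cl_death, "BREAST", "L1-C1")$confirm_kind, "DEATH")
  # ...unless the algorithm excludes death
  expect_equal(nrow(run_one(cl_death, "BREAST", "L1-C1-ed")), 0)

  # C4 reaches into the next calendar year, C1 does not
  cl_late <- claims_one_woman(outpatient = dplyr::bind_rows(
    out_dx("P1", "2013Q4"), out_dx("P1", "2014Q4")
  ))
  expect_equal(run_one(cl_late, "BREAST", "L1-C4")$confirm_kind,
               "SECOND_DIAGNOSIS")
  expect_equal(nrow(run_one(cl_late, "BREAST", "L1-C1")), 0)
})

test_that("surgery confirmation is necessary and sufficient in -su variants", {
  # surgery in the index quarter confirms; a second diagnosis does not
  cl <- claims_one_woman(
    outpatient = dplyr::bind_rows(out_dx("P1", "2013Q2"),
                                  out_dx("P1", "2013Q3")),
    procedures = proc_row("P1", "2013-05-10", "MASTECTOMY")
  )
  expect_equal(run_one(cl, "BREAST", "L1-C4-su")$confirm_kind, "SURGERY")

  cl_nosurg <- claims_one_woman(
    outpatient = dplyr::bind_rows(out_dx("P1", "2013Q2"),
                                  out_dx("P1", "2013Q3"))
  )
  expect_equal(nrow(run_one(cl_nosurg, "BREAST", "L1-C4-su")), 0)

  # either colorectal surgery class qualifies
  cl_endo <- make_claims(
    persons = person_row("P1"),
    outpatient = out_dx("P1", "2013Q2", icd = "C18.7"),
    procedures = proc_row("P1", "2013-08-01", "ENDOSCOPY")
  )
  expect_equal(run_one(cl_endo, "COLORECTAL", "L1-C4-su")$confirm_kind,
               "SURGERY")

  # prostate has no surgical confirmatory event
  cl_m <- make_claims(persons = person_row("P1", sex = "M"),
                      outpatient = out_dx("P1", "2013Q2", icd = "C61"))
  expect_error(run_one(cl_m, "PROSTATE", "L1-C4-su"),
               class = "oncoclaims_incompatible_error")
})

test_that("sex-incompatible diagnoses are skipped and dual cancers counted", {
  cl <- make_claims(
    persons = dplyr::bind_rows(person_row("W1"), person_row("M1", sex = "M")),
    outpatient = dplyr::bind_rows(
      out_dx("W1", "2013Q1"), out_dx("W1", "2013Q2"),          # breast
      out_dx("W1", "2013Q1", icd = "C18.4"),                   # colorectal
      out_dx("W1", "2013Q2", icd = "C18.4"),
      out_dx("M1", "2013Q1"), out_dx("M1", "2013Q2")           # C50 on a man
    )
  )
  cohort <- cohort_of(cl)
  breast <- identify_incident_cases(cl, cohort, "BREAST", "L1-C1")
  colo <- identify_incident_cases(cl, cohort, "COLORECTAL", "L1-C1")
  expect_equal(breast$person_id, "W1")   # M1 skipped for a female-only site
  expect_equal(colo$person_id, "W1")     # same woman counted in each entity
  expect_equal(nrow(dplyr::bind_rows(breast, colo)), 2)
})

test_that("identification is idempotent and empty input yields empty output", {
  cl <- random_small_claims(10)
  cohort <- cohort_of(cl)
  a <- identify_incident_cases(cl, cohort, "COLORECTAL", "L2-C1")
  b <- identify_incident_cases(cl, cohort, "COLORECTAL", "L2-C1")
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(identify_incident_cases(empty_claims(),
                                            cohort_of(empty_claims()),
                                            "BREAST", "L1-C1")), 0)
})

test_that("the engine matches the brute-force oracle on random populations", {
  set.seed(20061231)
  grid <- algorithm_grid()
  for (i in 1:60) {
    cl <- random_small_claims(n_persons = sample(1:20, 1),
                              n_events = sample(10:60, 1))
    cohort <- cohort_of(cl)
    site <- sample(cancer_sites(), 1)
    labels <- names(grid)
    if (site == "PROSTATE") labels <- labels[!grepl("-su$", labels)]
    label <- sample(labels, 1)
    got <- identify_incident_cases(cl, cohort, site, grid[[label]])
    expect_identical(got$person_id,
                     oracle_identify(cl, cohort, site, grid[[label]]),
                     label = sprintf("instance %d: %s %s", i, site, label))
  }
})
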