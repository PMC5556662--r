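test_that("crude cumulative incidence is cases per 100,000 persons", {
  expect_equal(round_report(crude_cumulative_incidence(10312, 4093251)),
               251.9)
  expect_equal(round_report(crude_cumulative_incidence(6513, 6763549)), 96.3)
  expect_equal(crude_cumulative_incidence(0, 1000), 0)
  expect_error(crude_cumulative_incidence(1, 0),
               class = "oncoclaims_data_error")
  expect_error(crude_cumulative_incidence(11, 10),
               class = "oncoclaims_data_error")
})

test_that("reporting rounds half away from zero", {
  expect_equal(round_report(c(1.25, -1.25, 2.04, -2.05)),
               c(1.3, -1.3, 2.0, -2.1))
})

test_that("the 1976 European Standard Population is well formed", {
  std <- esp1976()
  expect_equal(nrow(std), 18)
  expect_equal(sum(std$weight), 1e5)
  expect_equal(std$weight[std$age_band == "0-4"], 8000)
  expect_equal(std$weight[std$age_band == "85+"], 1000)
  # bands partition all ages
  expect_equal(as.character(age_band(c(0, 4, 5, 52, 84, 85, 103))),
               c("0-4", "0-4", "5-9", "50-54", "80-84", "85+", "85+"))
})

test_that("direct standardisation reduces to the weighted-rate formula", {
  std <- esp1976()
  # equal rates in every band: the standardised rate is that common rate
  data_eq <- tibble::tibble(age_band = std$age_band, cases = 2,
                            persons = 1000)
  expect_equal(age_standardized_cumulative_incidence(data_eq, std), 200)

  # a single populated band contributes weight * rate
  one <- tibble::tibble(age_band = "60-64", cases = 5, persons = 1000)
  expect_warning(got <- age_standardized_cumulative_incidence(one, std),
                 "empty age band")
  expect_equal(got, 5000 * (5 / 1000))  # w(60-64) = 5000

  # three-band fixture, hand-computed:
  # 7000 * 3/1000 + 5000 * 5/500 + 3000 * 2/200 = 21 + 50 + 30 = 101
  three <- tibble::tibble(age_band = c("50-54", "60-64", "70-74"),
                          cases = c(3, 5, 2), persons = c(1000, 500, 200))
  expect_equal(
    suppressWarnings(age_standardized_cumulative_incidence(three, std)),
    101
  )

  # invariant to uniform scaling of numerators and denominators
  scaled <- dplyr::mutate(three, cases = cases * 7, persons = persons * 7)
  expect_equal(
    suppressWarnings(age_standardized_cumulative_incidence(scaled, std)),
    101
  )

  expect_error(
    age_standardized_cumulative_incidence(
      tibble::tibble(age_band = "50-54", cases = 1, persons = 0), std
    ),
    class = "oncoclaims_data_error"
  )
})

test_that("percent differences reproduce the reporting convention", {
  expect_equal(round_report(percent_difference(138.7, 119.3)), 16.3)
  expect_equal(round_report(percent_difference(95.1, 98.0)), -3.0)
  expect_equal(percent_difference(42, 42), 0)
  expect_error(percent_difference(10, 0), class = "oncoclaims_data_error")
  # algebraic identity: pd(a, b) = -pd(b, a) * a / b
  set.seed(3)
  a <- runif(50, 10, 300)
  b <- runif(50, 10, 300)
  expect_equal(percent_difference(a, b),
               -percent_difference(b, a) * a / b)
})

make_result_fixture <- function() {
  persons <- dplyr::bind_rows(
    purrr::map(1:30, ~ person_row(sprintf("F%02d", .x), sex = "F",
                                  birth_year = sample(1935:1975, 1),
                                  state = sample(c("NI", "BY", "SN"), 1))),
    purrr::map(1:20, ~ person_row(sprintf("M%02d", .x), sex = "M",
                                  birth_year = sample(1935:1975, 1),
                                  state = sample(c("NI", "BY", "SN"), 1)))
  )
  cohort <- persons |>
    dplyr::mutate(age = 2013L - birth_year, age_band = age_band(age)) |>
    dplyr::select(person_id, sex, birth_year, age, age_band, state,
                  death_date)
  cases <- tibble::tibble(
    person_id = c("F01", "F02", "M01", "M02", "M03"),
    site = "COLORECTAL", algorithm_label = "L1-C1",
    index_quarter = "2013Q2", index_setting = "OUTPATIENT",
    confirm_kind = "SECOND_DIAGNOSIS"
  )
  class(cases) <- c("incident_cases", class(cases))
  list(cohort = cohort, cases = cases)
}

test_that("stratified results partition numerators and denominators", {
  set.seed(8)
  fx <- make_result_fixture()
  res <- stratified_results(fx$cases, fx$cohort)

  overall <- dplyr::filter(res, stratum_type == "overall")
  expect_equal(nrow(overall), 1)
  expect_equal(overall$numerator, 5)
  expect_equal(overall$denominator, 50)
  expect_equal(overall$cci, 1e5 * 5 / 50)

  by_sex <- dplyr::filter(res, stratum_type == "sex")
  expect_setequal(by_sex$stratum_value, c("F", "M"))
  expect_equal(sum(by_sex$numerator), overall$numerator)
  expect_equal(sum(by_sex$denominator), overall$denominator)
  expect_equal(by_sex$numerator[by_sex$stratum_value == "F"], 2)
  expect_equal(by_sex$numerator[by_sex$stratum_value == "M"], 3)

  by_state <- dplyr::filter(res, stratum_type == "state")
  expect_equal(nrow(by_state), 16)
  expect_equal(sum(by_state$numerator), overall$numerator)
  expect_equal(sum(by_state$denominator), overall$denominator)
})

test_that("strata = overall gives one row per site and algorithm", {
  set.seed(8)
  fx <- make_result_fixture()
  res <- stratified_results(fx$cases, fx$cohort, strata = "overall")
  expect_equal(nrow(res), 1)
  expect_equal(res$stratum_value, "ALL")
})

test_that("benchmark comparison joins strata and computes differences", {
  set.seed(8)
  fx <- make_result_fixture()
  res <- stratified_results(fx$cases, fx$cohort, strata = c("overall", "sex"))
  bench <- tibble::tibble(
    site = "COLORECTAL", sex = c("ALL", "F", "M"), state = "ALL",
    aci = c(100, 80, 120)
  )
  cmp <- compare_benchmark(res, bench)
  expect_equal(nrow(cmp), 3)
  row_f <- dplyr::filter(cmp, stratum_value == "F")
  expect_equal(row_f$registry_aci, 80)
  expect_equal(row_f$pct_diff,
               percent_difference(row_f$claims_aci, 80))
})

test_that("validation metrics score identified cases against truth", {
  # contingency 8 TP / 2 FP / 2 FN assembled explicitly
  ids_tp <- sprintf("T%02d", 1:8)
  ids_fp <- c("X01", "X02")
  ids_fn <- c("N01", "N02")
  all_ids <- c(ids_tp, ids_fp, ids_fn, "Z01")
  cohort <- tibble::tibble(person_id = all_ids, sex = "F",
                           birth_year = 1950L, age = 63L,
                           age_band = age_band(63), state = "NI",
                           death_date = as.Date(NA))
  truth <- tibble::tibble(
    person_id = all_ids, site = "BREAST",
    true_onset_quarter = NA_character_,
    case_type = dplyr::case_when(
      person_id %in% c(ids_tp, ids_fn) ~ "INCIDENT_2013",
      person_id %in% ids_fp ~ "PREVALENT_AT_START",
      TRUE ~ "NONE"
    )
  )
  cases <- tibble::tibble(
    person_id = c(ids_tp, ids_fp), site = "BREAST",
    algorithm_label = "L1-C1", index_quarter = "2013Q1",
    index_setting = "OUTPATIENT", confirm_kind = "SECOND_DIAGNOSIS"
  )
  vm <- validation_metrics(cases, truth, cohort, "BREAST", "L1-C1")
  expect_equal(c(vm$tp, vm$fp, vm$fn), c(8, 2, 2))
  expect_equal(vm$sensitivity, 0.8)
  expect_equal(vm$ppv, 0.8)

  td <- tidy(vm)
  expect_equal(td$value[td$metric == "ppv"], 0.8)
  gl <- glance(vm)
  expect_equal(gl$tp, 8)

  # all identified prevalent: PPV 0; nobody truly incident: sensitivity NA
  truth0 <- dplyr::mutate(truth, case_type = dplyr::if_else(
    person_id %in% c(ids_tp, ids_fp), "PREVALENT_AT_START", "NONE"
  ))
  vm0 <- validation_metrics(cases, truth0, cohort, "BREAST", "L1-C1")
  expect_equal(vm0$ppv, 0)
  expect_true(is.na(vm0$sensitivity))
})

test_that("autoplot methods return ggplot objects", {
  set.seed(8)
  fx <- make_result_fixture()
  res <- stratified_results(fx$cases, fx$cohort, strata = "overall")
  expect_s3_class(autoplot(res), "ggplot")
  bench <- tibble::tibble(site = "COLORECTAL", sex = "ALL", state = "ALL",
                          aci = 100)
  cmp <- compare_benchmark(res, bench)
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(autoplot(res, benchmark = bench), "ggplot")
})
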