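test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_persons = 800, seed = 77)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  for (tab in names(a)) {
    expect_identical(as.data.frame(a[[tab]]), as.data.frame(b[[tab]]))
  }
  # and the seed matters
  c <- generate_population(cfg, seed = 78)
  expect_false(identical(as.data.frame(a$outpatient),
                         as.data.frame(c$outpatient)))
})

test_that("zero hazards and zero noise produce a cancer-free population", {
  pop <- generate_population(
    sim_config_perfect(n_persons = 400, seed = 5,
                       hazard_q = c(BREAST = 0, PROSTATE = 0,
                                    COLORECTAL = 0))
  )
  cancer <- pop$outpatient |>
    dplyr::filter(grepl("^C(50|61|18|19|20|21)", .data$icd_code))
  expect_equal(nrow(cancer), 0)
  expect_equal(nrow(pop$inpatient), 0)
  expect_true(all(pop$ground_truth$case_type == "NONE"))
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(p_female = 1.2), class = "oncoclaims_config_error")
  expect_error(
    sim_config(age_distribution = rep(1, 18)),
    class = "oncoclaims_config_error"
  )
  expect_error(
    sim_config(disease = list(BREAST = list(coding = list(p_surgery = -0.1)))),
    class = "oncoclaims_config_error"
  )
})

test_that("generated tables satisfy the claims-model invariants", {
  pop <- generate_population(sim_config(n_persons = 4000, seed = 12))

  # every event belongs to a generated person
  for (tab in c("spells", "outpatient", "inpatient", "procedures")) {
    expect_true(all(pop[[tab]]$person_id %in% pop$persons$person_id))
  }
  # ground truth covers every person x site
  expect_equal(nrow(pop$ground_truth), 3 * nrow(pop$persons))

  # spells sorted, disjoint, and death never precedes the first spell
  sp <- pop$spells |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(
      ok = all(diff(as.integer(start)) > 0) &&
        all(start[-1] > end[-dplyr::n()]) && all(start <= end),
      first_start = min(start)
    )
  expect_true(all(sp$ok))
  died <- dplyr::inner_join(pop$persons, sp, by = "person_id") |>
    dplyr::filter(!is.na(death_date))
  expect_true(all(died$death_date >= died$first_start))

  # no diagnosis before the first-spell year or after the death quarter
  first_year <- sp |>
    dplyr::transmute(person_id,
                     first_qi = quarter_index(lubridate::year(first_start), 1))
  death_qi <- pop$persons |>
    dplyr::transmute(person_id,
                     death_qi = ifelse(is.na(death_date), Inf,
                                       date_to_quarter(death_date)))
  dx_q <- dplyr::bind_rows(
    dplyr::transmute(pop$outpatient, person_id,
                     qi = parse_quarter(quarter)),
    dplyr::transmute(pop$inpatient, person_id,
                     qi = date_to_quarter(discharge_date))
  ) |>
    dplyr::inner_join(first_year, by = "person_id") |>
    dplyr::inner_join(death_qi, by = "person_id")
  expect_true(all(dx_q$qi >= dx_q$first_qi))
  expect_true(all(dx_q$qi <= dx_q$death_qi))
})

test_that("incident-in-study-year fraction follows the closed form", {
  h <- 0.001
  n <- 20000
  pop <- generate_population(
    sim_config_perfect(n_persons = n, seed = 31,
                       hazard_q = c(BREAST = h, PROSTATE = h,
                                    COLORECTAL = h))
  )
  p4 <- 1 - (1 - h)^4  # incidence over the four study-year quarters
  truth <- dplyr::inner_join(pop$ground_truth, pop$persons, by = "person_id")
  for (s in cancer_sites()) {
    elig <- cancer_site(s)$eligible_sexes
    t_s <- dplyr::filter(truth, site == s, sex %in% elig)
    phat <- mean(t_s$case_type == "INCIDENT_2013")
    half <- 1.96 * sqrt(p4 * (1 - p4) / nrow(t_s))
    expect_lt(abs(phat - p4), half + 1e-9, label = s)
  }
})

test_that("suspected-only coding hits the configured rate", {
  cfg <- sim_config(n_persons = 20000, seed = 44)
  pop <- generate_population(cfg)
  v <- cfg$disease$BREAST$coding$p_suspected_only
  women <- pop$persons$person_id[pop$persons$sex == "F"]
  truth_b <- dplyr::filter(pop$ground_truth, site == "BREAST",
                           person_id %in% women)
  disease_free <- truth_b$person_id[
    truth_b$case_type %in% c("NONE", "SUSPECTED_ONLY")
  ]
  breast_dx <- dplyr::filter(pop$outpatient,
                             icd_matches_site(icd_code, "BREAST"))
  v_only <- breast_dx |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(v_only = all(certainty == "V")) |>
    dplyr::filter(v_only)
  n_free <- length(disease_free)
  phat <- sum(v_only$person_id %in% disease_free) / n_free
  half <- 1.96 * sqrt(v * (1 - v) / n_free)
  expect_lt(abs(phat - v), half)
  # and suspected-only labels carry no onset quarter
  expect_true(all(is.na(
    pop$ground_truth$true_onset_quarter[
      pop$ground_truth$case_type == "SUSPECTED_ONLY"
    ]
  )))
})

test_that("recurrence latency sampling matches its configured mean", {
  m <- 6
  cfg <- sim_config(
    n_persons = 3000, seed = 60,
    p_sex_missing = 0, p_birth_year_missing = 0,
    p_state_foreign = 0, p_state_missing = 0,
    enrollment = list(p_late_entry = 0, p_early_exit = 0, p_gap = 0),
    mortality = list(annual_base = 0, annual_growth = 0),
    benign_dx_mean = 0,
    disease = list(
      BREAST = list(hazard_q = rep(0, 18), p_prevalent = rep(0, 18),
                    coding = list(p_suspected_only = 0, p_excluded_dx = 0)),
      PROSTATE = list(hazard_q = rep(0, 18), p_prevalent = rep(0, 18),
                      coding = list(p_suspected_only = 0, p_excluded_dx = 0)),
      COLORECTAL = list(
      hazard_q = rep(0, 18), p_prevalent = rep(1, 18),
      p_recurrence = 1, recurrence_mean_latency_q = m, fatality_q = 0,
      coding = list(p_index_coded = 1, p_index_inpatient = 0,
                    p_followup_g = 0, p_ancillary = 0, p_z_post = 0,
                    p_history_miscode = 0, p_g_prevalent = 0,
                    p_z_prevalent = 0, p_suspected_only = 0,
                    p_excluded_dx = 0, p_surgery = 0)
      )
    )
  )
  pop <- generate_population(cfg)
  # with index-only coding, each within-span recurrence leaves exactly one
  # certain diagnosis at its recurrence quarter
  offsets <- dplyr::filter(pop$outpatient,
                           icd_matches_site(icd_code, "COLORECTAL")) |>
    dplyr::mutate(off = parse_quarter(quarter) - quarter_index(2006, 1)) |>
    dplyr::pull(off)
  # closed-form mean of the latency distribution truncated to the span
  p <- 1 / m
  k <- 0:35
  pmf <- p * (1 - p)^k
  exp_mean <- sum(k * pmf) / sum(pmf)
  se <- sqrt(sum((k - exp_mean)^2 * pmf / sum(pmf)) / length(offsets))
  expect_gt(length(offsets), 1000)
  expect_lt(abs(mean(offsets) - exp_mean), 4 * se)
})

test_that("the ground-truth benchmark standardises onsets correctly", {
  # hand-built population: three 2013 onsets concentrated in two age bands
  # of one state; direct standardisation done by hand in the comment below
  persons <- dplyr::bind_rows(
    purrr::map(1:40, ~ person_row(sprintf("A%02d", .x), sex = "F",
                                  birth_year = 1961L, state = "HB")),  # 50-54
    purrr::map(1:20, ~ person_row(sprintf("B%02d", .x), sex = "F",
                                  birth_year = 1951L, state = "HB")),  # 60-64
    purrr::map(1:10, ~ person_row(sprintf("C%02d", .x), sex = "F",
                                  birth_year = 1941L, state = "BY"))   # 70-74, no onsets
  )
  truth <- tidyr::expand_grid(person_id = persons$person_id,
                              site = cancer_sites()) |>
    dplyr::mutate(
      true_onset_quarter = dplyr::if_else(
        person_id %in% c("A01", "A02", "B01") & site == "BREAST",
        "2013Q2", NA_character_),
      case_type = dplyr::if_else(!is.na(true_onset_quarter),
                                 "INCIDENT_2013", "NONE")
    )
  pop <- structure(
    list(persons = persons,
         spells = tibble::tibble(person_id = persons$person_id,
                                 start = as.Date("2006-01-01"),
                                 end = as.Date("2014-12-31")),
         ground_truth = truth),
    config = sim_config(n_persons = 1, seed = 1),
    class = c("claims_tables", "list")
  )
  bench <- generate_registry_benchmark(pop)
  # weights: 50-54 -> 7000, 60-64 -> 5000 per 100,000
  # ACI = (7000 * 2/40 + 5000 * 1/20) * 100000 / 100000 = 350 + 250 = 600
  got <- bench$aci[bench$site == "BREAST" & bench$state == "ALL"]
  expect_equal(got, 600)
  expect_equal(bench$aci[bench$site == "BREAST" & bench$state == "HB"], 600)
  # a populated state without onsets reports zero; unpopulated states NA
  expect_equal(bench$aci[bench$site == "BREAST" & bench$state == "BY"], 0)
  other <- bench$aci[bench$site == "BREAST" &
                       !bench$state %in% c("ALL", "HB", "BY")]
  expect_true(all(is.na(other)))
  expect_true(all(bench$aci[bench$site == "PROSTATE"] == 0, na.rm = TRUE))
})
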