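# In-code fixture builders: tiny claims tables assembled row by row, and a
# fully random small population used for oracle-equivalence property tests.

empty_claims <- function() {
  list(
    persons = tibble::tibble(person_id = character(), sex = character(),
                             birth_year = integer(), state = character(),
                             death_date = as.Date(character())),
    spells = tibble::tibble(person_id = character(),
                            start = as.Date(character()),
                            end = as.Date(character())),
    outpatient = tibble::tibble(person_id = character(), quarter = character(),
                                icd_code = character(),
                                certainty = character()),
    inpatient = tibble::tibble(person_id = character(),
                               admission_date = as.Date(character()),
                               discharge_date = as.Date(character()),
                               icd_code = character(), dx_type = character()),
    procedures = tibble::tibble(person_id = character(),
                                date = as.Date(character()),
                                proc_class = character())
  )
}

# one fully covered person plus any events given as data frames
make_claims <- function(persons = NULL, spells = NULL, outpatient = NULL,
                        inpatient = NULL, procedures = NULL) {
  cl <- empty_claims()
  add <- function(base, extra) {
    if (is.null(extra)) return(base)
    dplyr::bind_rows(base, tibble::as_tibble(extra))
  }
  cl$persons <- add(cl$persons, persons)
  cl$spells <- add(cl$spells, spells)
  if (is.null(spells) && !is.null(persons)) {
    cl$spells <- tibble::tibble(person_id = cl$persons$person_id,
                                start = as.Date("2005-01-01"),
                                end = as.Date("2014-12-31"))
  }
  cl$outpatient <- add(cl$outpatient, outpatient)
  cl$inpatient <- add(cl$inpatient, inpatient)
  cl$procedures <- add(cl$procedures, procedures)
  structure(cl, class = c("claims_tables", "list"))
}

person_row <- function(id, sex = "F", birth_year = 1950L, state = "NI",
                       death_date = NA) {
  tibble::tibble(person_id = id, sex = sex,
                 birth_year = as.integer(birth_year), state = state,
                 death_date = as.Date(death_date))
}

out_dx <- function(id, quarter, icd = "C50.1", certainty = "G") {
  tibble::tibble(person_id = id, quarter = quarter, icd_code = icd,
                 certainty = certainty)
}

inp_dx <- function(id, discharge, icd = "C50.1", dx_type = "MAIN_DISCHARGE") {
  discharge <- as.Date(discharge)
  tibble::tibble(person_id = id, admission_date = discharge - 2,
                 discharge_date = discharge, icd_code = icd,
                 dx_type = dx_type)
}

proc_row <- function(id, date, proc_class) {
  tibble::tibble(person_id = id, date = as.Date(date),
                 proc_class = proc_class)
}

cohort_of <- function(claims) {
  claims$persons |>
    dplyr::filter(.data$sex %in% c("F", "M")) |>
    dplyr::mutate(age = 2013L - .data$birth_year,
                  age_band = age_band(.data$age)) |>
    dplyr::select("person_id", "sex", "birth_year", "age", "age_band",
                  "state", "death_date")
}

# random small population over 2006--2014: arbitrary diagnosis histories,
# including V/Z/A certainties, both inpatient types, surgeries and deaths
random_small_claims <- function(n_persons = 12, n_events = 40) {
  qs <- as.vector(outer(1:4, 2006:2014, function(q, y) sprintf("%dQ%d", y, q)))
  ids <- sprintf("R%02d", seq_len(n_persons))
  sex <- sample(c("F", "M"), n_persons, replace = TRUE)
  death <- as.Date(ifelse(runif(n_persons) < 0.25,
                          sprintf("%d-%02d-%02d", sample(2012:2014, n_persons, TRUE),
                                  sample(1:12, n_persons, TRUE),
                                  sample(1:28, n_persons, TRUE)),
                          NA))
  persons <- tibble::tibble(person_id = ids, sex = sex,
                            birth_year = sample(1925:1990, n_persons, TRUE),
                            state = sample(german_states(), n_persons, TRUE),
                            death_date = death)
  icds <- c("C50.1", "C50", "c50.9", "C61", "C18.2", "C19", "C20", "C21",
            "C22.0", "I10.90", "C340")
  k_out <- n_events
  outpatient <- tibble::tibble(
    person_id = sample(ids, k_out, replace = TRUE),
    quarter = sample(qs, k_out, replace = TRUE),
    icd_code = sample(icds, k_out, replace = TRUE),
    certainty = sample(c("G", "V", "Z", "A"), k_out, replace = TRUE,
                       prob = c(0.5, 0.15, 0.25, 0.1))
  )
  k_inp <- max(2, n_events %/% 4)
  inp_dis <- as.Date("2006-01-01") +
    sample.int(as.integer(as.Date("2014-12-31") - as.Date("2006-01-01")),
               k_inp, replace = TRUE)
  inpatient <- tibble::tibble(
    person_id = sample(ids, k_inp, replace = TRUE),
    admission_date = inp_dis - sample(0:5, k_inp, replace = TRUE),
    discharge_date = inp_dis,
    icd_code = sample(icds, k_inp, replace = TRUE),
    dx_type = sample(c("MAIN_DISCHARGE", "ANCILLARY"), k_inp, replace = TRUE)
  )
  k_pr <- max(2, n_events %/% 5)
  procedures <- tibble::tibble(
    person_id = sample(ids, k_pr, replace = TRUE),
    date = as.Date("2012-01-01") + sample.int(1090, k_pr, replace = TRUE),
    proc_class = sample(c("LUMPECTOMY", "MASTECTOMY", "ENDOSCOPY",
                          "COLORECTAL_SURGERY", "OTHER"), k_pr,
                        replace = TRUE)
  )
  make_claims(persons = persons, outpatient = outpatient,
              inpatient = inpatient, procedures = procedures)
}
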