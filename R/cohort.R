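#' Cohort eligibility specification
#'
#' Eligibility for the study population is assessed on a reference date
#' (default 2013-01-01): a person qualifies when the preceding
#' `required_years` are continuously insured, where continuity tolerates
#' coverage gaps of at most `max_gap_days` days (default 28 — gaps of *more*
#' than 28 days break continuity). The main analysis requires 7 years; the
#' sensitivity analyses use 1 year or the lookback length of each algorithm.
#'
#' @param reference_date Reference date (`Date` or ISO string).
#' @param required_years Minimum years of continuous insurance before the
#'   reference date.
#' @param max_gap_days Longest tolerated uncovered run of days.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(reference_date = "2013-01-01", required_years = 7,
                        max_gap_days = 28) {
  if (is.character(reference_date)) reference_date <- parse_iso_date(reference_date)
  stopifnot(required_years >= 1, max_gap_days >= 0)
  structure(
    list(reference_date = reference_date,
         required_years = as.integer(required_years),
         max_gap_days = as.integer(max_gap_days)),
    class = "cohort_spec"
  )
}

#' Continuous-insurance check
#'
#' Tests, per person, whether the window from `reference_date -
#' required_years` to `reference_date` is covered by insurance spells such
#' that every uncovered run of days inside the window is at most
#' `max_gap_days` long, and the reference date itself is covered.
#'
#' @param spells Tibble of insurance spells (`person_id`, `start`, `end`),
#'   closed date intervals, disjoint within person.
#' @param spec A [cohort_spec()].
#' @param person_ids Optional character vector fixing the result order and
#'   including persons without any spell (who are never continuously
#'   insured).
#' @return A tibble `person_id`, `continuous` (logical).
#' @export
is_continuously_insured <- function(spells, spec = cohort_spec(),
                                    person_ids = NULL) {
  ref <- spec$reference_date
  win_start <- ref - lubridate::years(spec$required_years)
  res <- spells |>
    dplyr::filter(.data$end >= win_start, .data$start <= ref) |>
    dplyr::mutate(start = pmax(.data$start, win_start),
                  end = pmin(.data$end, ref)) |>
    dplyr::arrange(.data$person_id, .data$start) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      continuous = covers_window(.data$start, .data$end, win_start, ref,
                                 spec$max_gap_days),
      .groups = "drop"
    )
  if (!is.null(person_ids)) {
    res <- tibble::tibble(person_id = person_ids) |>
      dplyr::left_join(res, by = "person_id") |>
      dplyr::mutate(continuous = !is.na(.data$continuous) & .data$continuous)
  }
  res
}

# spells already clipped to [win_start, ref], sorted, disjoint.
# Gap = wholly uncovered calendar days strictly between covered days (or
# between the window start and the first covered day).
covers_window <- function(start, end, win_start, ref, max_gap) {
  if (length(start) == 0) return(FALSE)
  head_gap <- as.integer(start[1] - win_start)
  if (head_gap > max_gap) return(FALSE)
  if (length(start) > 1) {
    mid_gaps <- as.integer(start[-1] - end[-length(end)]) - 1L
    if (any(mid_gaps > max_gap)) return(FALSE)
  }
  # the reference date itself must be covered
  end[length(end)] >= ref
}

#' Build the study cohort
#'
#' Applies the eligibility rules in a fixed order — insurance continuity,
#' then non-missing sex, birth year, state, and German residence — so that
#' each excluded person is tallied under the first rule it fails. The
#' resulting tibble is the denominator population for incidence estimation.
#'
#' @param persons Persons tibble (see [read_claims_tables()]).
#' @param spells Spells tibble.
#' @param spec A [cohort_spec()].
#' @return A tibble of class `cohort` with columns `person_id`, `sex`,
#'   `birth_year`, `age` (at the reference year), `age_band`, `state`,
#'   `death_date`, and attributes `exclusions` (named integer tally in rule
#'   order) and `spec`.
#' @examples
#' \dontrun{
#' claims <- generate_population(sim_config(n_persons = 2000, seed = 1))
#' cohort <- build_cohort(claims$persons, claims$spells, cohort_spec())
#' attr(cohort, "exclusions")
#' }
#' @export
build_cohort <- function(persons, spells, spec = cohort_spec()) {
  cont <- is_continuously_insured(spells, spec, person_ids = persons$person_id)
  ref_year <- lubridate::year(spec$reference_date)
  status <- persons |>
    dplyr::left_join(cont, by = "person_id") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        !.data$continuous ~ "not_continuously_insured",
        .data$sex == "MISSING" ~ "missing_sex",
        is.na(.data$birth_year) ~ "missing_birth_year",
        .data$state == "MISSING" ~ "missing_state",
        .data$state == "FOREIGN" ~ "foreign_residence",
        TRUE ~ "eligible"
      )
    )
  reasons <- c("not_continuously_insured", "missing_sex", "missing_birth_year",
               "missing_state", "foreign_residence")
  tally <- purrr::map_int(reasons, ~ sum(status$reason == .x))
  names(tally) <- reasons
  cohort <- status |>
    dplyr::filter(.data$reason == "eligible") |>
    dplyr::mutate(age = ref_year - .data$birth_year,
                  age_band = age_band(.data$age)) |>
    dplyr::select("person_id", "sex", "birth_year", "age", "age_band",
                  "state", "death_date")
  structure(cohort, exclusions = tally, spec = spec,
            class = c("cohort", class(cohort)))
}

#' Site-specific denominator
#'
#' Counts cohort members whose sex is eligible for the site: women for
#' breast, men for prostate, everyone for colorectal.
#'
#' @param cohort A [build_cohort()] result.
#' @param site A [cancer_site()] or site name.
#' @return Integer count.
#' @export
site_denominator <- function(cohort, site) {
  site <- as_cancer_site(site)
  sum(cohort$sex %in% site$eligible_sexes)
}
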