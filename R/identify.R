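#' @keywords internal
#' Pool all diagnosis events of one site onto the quarterly grid.
#'
#' Outpatient diagnoses qualify with certainty G in any context and with
#' certainty Z (status post) in the lookback and confirmation contexts; V
#' (suspected) and A (excluded) never qualify. Inpatient diagnoses qualify
#' as index events only as main discharge diagnoses; ancillary hospital
#' diagnoses additionally qualify in the lookback and confirmation contexts.
#' Inpatient stays are assigned to the quarter of their discharge date.
site_dx_events <- function(claims, site) {
  site <- as_cancer_site(site)
  out <- claims$outpatient |>
    dplyr::filter(icd_matches_site(.data$icd_code, site),
                  .data$certainty %in% c("G", "Z")) |>
    dplyr::transmute(.data$person_id, qi = parse_quarter(.data$quarter),
                     index_ok = .data$certainty == "G",
                     setting = "OUTPATIENT")
  inp <- claims$inpatient |>
    dplyr::filter(icd_matches_site(.data$icd_code, site)) |>
    dplyr::transmute(.data$person_id,
                     qi = date_to_quarter(.data$discharge_date),
                     index_ok = .data$dx_type == "MAIN_DISCHARGE",
                     setting = "INPATIENT")
  dplyr::bind_rows(out, inp)
}

#' Find index quarters for a site
#'
#' The index quarter of a person is the earliest quarter of the study year
#' containing an index-qualifying diagnosis of the site: an outpatient
#' diagnosis coded "certain" (G) or a main hospital discharge diagnosis.
#' When both settings contribute to the same earliest quarter, the case is
#' reported as outpatient-indexed.
#'
#' @param claims A `claims_tables` list.
#' @param site A [cancer_site()] or name.
#' @param person_ids Optional restriction to these persons.
#' @param study_year Calendar year scanned for index events (default 2013).
#' @return Tibble `person_id`, `index_qi` (quarter index), `index_quarter`
#'   (`"YYYYQn"`), `index_setting`; persons without a qualifying diagnosis
#'   are absent.
#' @export
find_index_quarter <- function(claims, site, person_ids = NULL,
                               study_year = 2013) {
  dx <- site_dx_events(claims, site)
  if (!is.null(person_ids)) dx <- dplyr::filter(dx, .data$person_id %in% person_ids)
  q_lo <- quarter_index(study_year, 1L)
  q_hi <- quarter_index(study_year, 4L)
  cand <- dx |>
    dplyr::filter(.data$index_ok, .data$qi >= q_lo, .data$qi <= q_hi)
  if (nrow(cand) == 0) {
    return(tibble::tibble(person_id = character(), index_qi = integer(),
                          index_quarter = character(),
                          index_setting = character()))
  }
  cand |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      index_qi = min(.data$qi),
      index_setting = if (any(.data$setting[.data$qi == min(.data$qi)] ==
                                "OUTPATIENT")) "OUTPATIENT" else "INPATIENT",
      .groups = "drop"
    ) |>
    dplyr::mutate(index_quarter = format_quarter(.data$index_qi)) |>
    dplyr::select("person_id", "index_qi", "index_quarter", "index_setting")
}

#' Lookback (washout) screening
#'
#' A candidate is retained only if the `4 * lookback_years` quarters
#' immediately preceding the index quarter contain no qualifying diagnosis
#' of the site — here G- or Z-coded outpatient diagnoses and main-discharge
#' or ancillary inpatient diagnoses all count, so that prevalent and
#' recurrent disease under routine surveillance coding is screened out.
#'
#' @param claims A `claims_tables` list.
#' @param site A [cancer_site()] or name.
#' @param index Tibble with `person_id` and `index_qi` (from
#'   [find_index_quarter()]).
#' @param lookback_years Lookback length L in years; the screened window is
#'   `[index_qi - 4L, index_qi - 1]`.
#' @return `index` with an added logical column `passes_lookback`.
#' @export
passes_lookback <- function(claims, site, index, lookback_years) {
  lb_q <- 4L * as.integer(lookback_years)
  hits <- site_dx_events(claims, site) |>
    dplyr::inner_join(index, by = "person_id") |>
    dplyr::filter(.data$qi >= .data$index_qi - lb_q,
                  .data$qi <= .data$index_qi - 1L) |>
    dplyr::distinct(.data$person_id)
  index |>
    dplyr::mutate(passes_lookback = !.data$person_id %in% hits$person_id)
}

#' Confirmation-window evaluation
#'
#' Applies the confirmatory-event rule of an [algorithm_spec()] to index
#' candidates:
#'
#' * no confirmation required (C0): every candidate passes with kind
#'   `NONE_REQUIRED`;
#' * surgery required (`-su`): a procedure of the site's surgery classes in
#'   quarters `[index, index + C]` is necessary and sufficient
#'   (kind `SURGERY`);
#' * otherwise a second qualifying diagnosis in `[index + 1, index + C]`
#'   confirms (`SECOND_DIAGNOSIS`; the index quarter is excluded so the
#'   index record can never confirm itself), or failing that death in
#'   `[index, index + C]` when death is an admissible event (`DEATH`).
#'
#' Surgery confirmation is undefined for prostate cancer and raises an
#' incompatibility error.
#'
#' @param claims A `claims_tables` list.
#' @param site A [cancer_site()] or name.
#' @param index Tibble with `person_id`, `index_qi`.
#' @param spec An [algorithm_spec()] or label.
#' @return `index` with an added `confirm_kind` column
#'   (`NONE_REQUIRED` / `SECOND_DIAGNOSIS` / `DEATH` / `SURGERY`, or `NA`
#'   where confirmation fails).
#' @export
passes_confirmation <- function(claims, site, index, spec) {
  site <- as_cancer_site(site)
  spec <- as_algorithm_spec(spec)
  cq <- spec$confirmation_quarters

  if (!spec$require_confirmation) {
    return(dplyr::mutate(index, confirm_kind = "NONE_REQUIRED"))
  }

  if (spec$require_surgery_confirm) {
    if (length(site$surgery_classes) == 0) {
      rlang::abort(
        sprintf("algorithm '%s' requires surgical confirmation, undefined for site %s",
                spec$label, site$name),
        class = "oncoclaims_incompatible_error"
      )
    }
    surg <- claims$procedures |>
      dplyr::filter(.data$proc_class %in% site$surgery_classes) |>
      dplyr::mutate(qi = date_to_quarter(.data$date)) |>
      dplyr::inner_join(index, by = "person_id") |>
      dplyr::filter(.data$qi >= .data$index_qi,
                    .data$qi <= .data$index_qi + cq) |>
      dplyr::distinct(.data$person_id)
    return(dplyr::mutate(
      index,
      confirm_kind = dplyr::if_else(.data$person_id %in% surg$person_id,
                                    "SURGERY", NA_character_)
    ))
  }

  second <- site_dx_events(claims, site) |>
    dplyr::inner_join(index, by = "person_id") |>
    dplyr::filter(.data$qi >= .data$index_qi + 1L,
                  .data$qi <= .data$index_qi + cq) |>
    dplyr::distinct(.data$person_id)

  res <- dplyr::mutate(
    index,
    confirm_kind = dplyr::if_else(.data$person_id %in% second$person_id,
                                  "SECOND_DIAGNOSIS", NA_character_)
  )

  if (spec$allow_death_confirm) {
    death_qi <- claims$persons |>
      dplyr::filter(!is.na(.data$death_date)) |>
      dplyr::transmute(.data$person_id,
                       death_qi = date_to_quarter(.data$death_date))
    res <- res |>
      dplyr::left_join(death_qi, by = "person_id") |>
      dplyr::mutate(
        confirm_kind = dplyr::case_when(
          !is.na(.data$confirm_kind) ~ .data$confirm_kind,
          !is.na(.data$death_qi) & .data$death_qi >= .data$index_qi &
            .data$death_qi <= .data$index_qi + cq ~ "DEATH",
          TRUE ~ NA_character_
        )
      ) |>
      dplyr::select(-"death_qi")
  }
  res
}

#' Identify incident cancer cases
#'
#' Runs the full case definition of one algorithm for one site over a study
#' cohort: (1) the earliest index-qualifying diagnosis quarter in the study
#' year, (2) a diagnosis-free lookback window, (3) a confirmatory event in
#' the confirmation window. A person contributes at most one case per site;
#' a person with two incident cancers (e.g. breast and colorectal) is
#' counted under each site.
#'
#' @param claims A `claims_tables` list.
#' @param cohort A [build_cohort()] result (or tibble with `person_id`,
#'   `sex`).
#' @param site A [cancer_site()] or name.
#' @param spec An [algorithm_spec()] or grid label such as `"L7-C1"`.
#' @param study_year Year in which index events are sought (default 2013).
#' @return A tibble of class `incident_cases`: `person_id`, `site`,
#'   `algorithm_label`, `index_quarter`, `index_setting`, `confirm_kind`.
#' @examples
#' \dontrun{
#' claims <- generate_population(sim_config(n_persons = 5000, seed = 7))
#' cohort <- build_cohort(claims$persons, claims$spells)
#' identify_incident_cases(claims, cohort, "BREAST", "L7-C1")
#' }
#' @export
identify_incident_cases <- function(claims, cohort, site, spec,
                                    study_year = 2013) {
  site <- as_cancer_site(site)
  spec <- as_algorithm_spec(spec)
  eligible <- cohort$person_id[cohort$sex %in% site$eligible_sexes]

  index <- find_index_quarter(claims, site, eligible, study_year)
  kept <- passes_lookback(claims, site, index, spec$lookback_years) |>
    dplyr::filter(.data$passes_lookback)
  confirmed <- passes_confirmation(claims, site, kept, spec) |>
    dplyr::filter(!is.na(.data$confirm_kind))

  out <- confirmed |>
    dplyr::transmute(.data$person_id, site = site$name,
                     algorithm_label = spec$label, .data$index_quarter,
                     .data$index_setting, .data$confirm_kind) |>
    dplyr::arrange(.data$person_id)
  class(out) <- c("incident_cases", class(out))
  out
}

#' Identify cases across sites and algorithms
#'
#' Convenience wrapper running [identify_incident_cases()] over a selection
#' of sites and grid algorithms and row-binding the results. With
#' `algorithms = "all"`, surgery-required algorithms are skipped for
#' prostate (no surgical confirmatory event is defined for that site, the
#' grid's N/A cells); an explicitly requested incompatible pair still
#' errors.
#'
#' @param claims A `claims_tables` list.
#' @param cohort A [build_cohort()] result.
#' @param sites Character vector of site names, or `"all"`.
#' @param algorithms Character vector of grid labels, or `"all"`.
#' @param study_year Study year.
#' @return Combined `incident_cases` tibble.
#' @export
identify_cases <- function(claims, cohort, sites = "all", algorithms = "all",
                           study_year = 2013) {
  if (identical(sites, "all")) sites <- cancer_sites()
  grid <- algorithm_grid()
  skip_na_cells <- identical(algorithms, "all")
  if (skip_na_cells) algorithms <- names(grid)
  bad <- setdiff(algorithms, names(grid))
  if (length(bad)) {
    rlang::abort(paste("unknown algorithm label(s):",
                       paste(bad, collapse = ", ")),
                 class = "oncoclaims_config_error")
  }
  combos <- tidyr::expand_grid(site = sites, label = algorithms)
  if (skip_na_cells) {
    combos <- combos |>
      dplyr::filter(!(purrr::map_lgl(.data$label,
                                     ~ grid[[.x]]$require_surgery_confirm) &
                        .data$site == "PROSTATE"))
  }
  out <- purrr::pmap(combos, function(site, label) {
    identify_incident_cases(claims, cohort, site, grid[[label]], study_year)
  }) |>
    purrr::list_rbind()
  class(out) <- c("incident_cases", class(out))
  out
}
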