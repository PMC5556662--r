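#' Crude cumulative incidence
#'
#' Cases per 100,000 cohort members in the study year. Denominators are
#' person counts fixed at cohort entry, matching the cumulative-incidence
#' design (no person-time).
#'
#' @param numerator Case count(s).
#' @param denominator Person count(s), > 0.
#' @return Unrounded rate(s) per 100,000; use [round_report()] when
#'   reporting.
#' @examples
#' round_report(crude_cumulative_incidence(10312, 4093251))  # 251.9
#' @export
crude_cumulative_incidence <- function(numerator, denominator) {
  if (any(denominator == 0)) {
    rlang::abort("crude cumulative incidence undefined for a zero denominator",
                 class = "oncoclaims_data_error")
  }
  if (any(numerator > denominator)) {
    rlang::abort("numerator exceeds denominator",
                 class = "oncoclaims_data_error")
  }
  1e5 * numerator / denominator
}

#' Reporting-layer rounding
#'
#' Printed incidence tables round half away from zero to one decimal; all
#' internal comparisons in this package operate on unrounded values and
#' rounding is applied only when reporting.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_report <- function(x, digits = 1) round_half_out(x, digits)

#' Direct age standardisation of cumulative incidence
#'
#' Weights band-specific rates by a standard population:
#' `ACI = sum_g w_g * (n_g / d_g)` with weights per 100,000 summing to
#' 100,000, so the result is again a rate per 100,000. Bands with an empty
#' denominator contribute 0 and are reported in a single warning; a band
#' with cases but no denominator is a data error.
#'
#' @param data Data frame with columns `age_band`, `cases`, `persons`
#'   (missing bands are treated as empty).
#' @param std Standard population as returned by [esp1976()].
#' @return Unrounded age-standardised rate per 100,000.
#' @export
age_standardized_cumulative_incidence <- function(data, std = esp1976()) {
  stopifnot(abs(sum(std$weight) - 1e5) < 1e-9)
  joined <- std |>
    dplyr::left_join(
      data |>
        dplyr::mutate(age_band = as.character(.data$age_band)) |>
        dplyr::group_by(.data$age_band) |>
        dplyr::summarise(cases = sum(.data$cases),
                         persons = sum(.data$persons), .groups = "drop"),
      by = dplyr::join_by(x$age_band == y$age_band)
    ) |>
    dplyr::mutate(cases = dplyr::coalesce(.data$cases, 0),
                  persons = dplyr::coalesce(.data$persons, 0))
  if (any(joined$cases > 0 & joined$persons == 0)) {
    rlang::abort("age band with cases but empty denominator",
                 class = "oncoclaims_data_error")
  }
  if (any(joined$cases > joined$persons)) {
    rlang::abort("age band with more cases than persons",
                 class = "oncoclaims_data_error")
  }
  empty <- joined$persons == 0 & joined$weight > 0
  if (any(empty)) {
    rlang::warn(sprintf(
      "empty age band(s) contribute 0 to the standardised rate: %s",
      paste(joined$age_band[empty], collapse = ", ")
    ))
  }
  rate <- dplyr::if_else(joined$persons > 0, joined$cases / joined$persons, 0)
  sum(joined$weight * rate) * 1e5 / sum(joined$weight)
}

#' Crude and age-standardised incidence by stratum
#'
#' Builds the full results table for the site x algorithm combinations
#' present in `cases`: for each requested stratification (overall, by sex,
#' by federal state) the case count, the person-count denominator restricted
#' to the site's eligible sexes, the crude cumulative incidence and the
#' directly age-standardised cumulative incidence. Sex strata are only
#' produced for sites with more than one eligible sex (colorectal); state
#' strata cover the 16 federal states.
#'
#' @param cases An `incident_cases` tibble (see [identify_incident_cases()]).
#' @param cohort A [build_cohort()] result.
#' @param std Standard population (default [esp1976()]).
#' @param strata Subset of `c("overall", "sex", "state")`.
#' @return A tibble of class `incidence_result` with columns `site`,
#'   `algorithm_label`, `stratum_type`, `stratum_value`, `numerator`,
#'   `denominator`, `cci`, `aci` (both unrounded, per 100,000).
#' @export
stratified_results <- function(cases, cohort, std = esp1976(),
                               strata = c("overall", "sex", "state")) {
  strata <- match.arg(strata, several.ok = TRUE)
  cases_attr <- cases |>
    dplyr::select("person_id", "site", "algorithm_label") |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(cohort), "person_id", "sex",
                    "state", "age_band"),
      by = "person_id"
    )
  combos <- dplyr::distinct(cases_attr, .data$site, .data$algorithm_label)
  cohort_tbl <- tibble::as_tibble(cohort)

  one_stratum <- function(site_name, label, stype, svalue) {
    site <- cancer_site(site_name)
    pop <- dplyr::filter(cohort_tbl, .data$sex %in% site$eligible_sexes)
    cas <- dplyr::filter(cases_attr, .data$site == site_name,
                         .data$algorithm_label == label)
    if (stype == "sex") {
      pop <- dplyr::filter(pop, .data$sex == svalue)
      cas <- dplyr::filter(cas, .data$sex == svalue)
    } else if (stype == "state") {
      pop <- dplyr::filter(pop, .data$state == svalue)
      cas <- dplyr::filter(cas, .data$state == svalue)
    }
    band_tab <- pop |>
      dplyr::count(.data$age_band, name = "persons") |>
      dplyr::left_join(dplyr::count(cas, .data$age_band, name = "cases"),
                       by = "age_band") |>
      dplyr::mutate(cases = dplyr::coalesce(.data$cases, 0L))
    den <- nrow(pop)
    num <- nrow(cas)
    tibble::tibble(
      site = site_name, algorithm_label = label, stratum_type = stype,
      stratum_value = svalue, numerator = num, denominator = den,
      cci = if (den > 0) 1e5 * num / den else NA_real_,
      aci = if (den > 0) {
        suppressWarnings(age_standardized_cumulative_incidence(band_tab, std))
      } else NA_real_
    )
  }

  proto <- tibble::tibble(
    site = character(), algorithm_label = character(),
    stratum_type = character(), stratum_value = character(),
    numerator = integer(), denominator = integer(),
    cci = double(), aci = double()
  )
  rows <- purrr::pmap(combos, function(site, algorithm_label) {
    site_def <- cancer_site(site)
    levels <- list()
    if ("overall" %in% strata) {
      levels <- c(levels, list(c("overall", "ALL")))
    }
    if ("sex" %in% strata && length(site_def$eligible_sexes) > 1) {
      levels <- c(levels, purrr::map(site_def$eligible_sexes,
                                     ~ c("sex", .x)))
    }
    if ("state" %in% strata) {
      levels <- c(levels, purrr::map(german_states(), ~ c("state", .x)))
    }
    purrr::map(levels, ~ one_stratum(site, algorithm_label, .x[1], .x[2])) |>
      purrr::list_rbind()
  })
  rows <- purrr::list_rbind(c(list(proto), rows))
  class(rows) <- c("incidence_result", class(rows))
  rows
}

#' Percent difference of two rates
#'
#' Relative difference of a claims-based estimate from a registry benchmark,
#' `100 * (claims - registry) / registry`. Reported to one decimal by the
#' reporting layer; the returned value is unrounded.
#'
#' @param claims_value,registry_value Numeric rates; `registry_value` must be
#'   non-zero.
#' @return Unrounded percent difference(s).
#' @examples
#' round_report(percent_difference(138.7, 119.3))  # 16.3
#' @export
percent_difference <- function(claims_value, registry_value) {
  if (any(registry_value == 0)) {
    rlang::abort("percent difference undefined against a zero registry value",
                 class = "oncoclaims_data_error")
  }
  100 * (claims_value - registry_value) / registry_value
}

#' Benchmark claims-based rates against registry rates
#'
#' Joins an [stratified_results()] table with a registry benchmark table
#' (`site`, `sex`, `state`, `aci`, as produced by
#' [generate_registry_benchmark()] or supplied from published registry
#' tables) and computes percent differences. Result strata are mapped onto
#' the benchmark convention: overall -> `sex = "ALL", state = "ALL"`, a sex
#' stratum -> that sex with `state = "ALL"`, a state stratum -> that state
#' with `sex = "ALL"`.
#'
#' @param results An `incidence_result` tibble.
#' @param benchmark Benchmark tibble (`site`, `sex`, `state`, `aci`).
#' @return A tibble of class `benchmark_comparison`: `site`,
#'   `algorithm_label`, `stratum_type`, `stratum_value`, `claims_aci`,
#'   `registry_aci`, `pct_diff` (unrounded). Strata without a benchmark row
#'   are dropped.
#' @export
compare_benchmark <- function(results, benchmark) {
  mapped <- results |>
    dplyr::mutate(
      bench_sex = dplyr::if_else(.data$stratum_type == "sex",
                                 .data$stratum_value, "ALL"),
      bench_state = dplyr::if_else(.data$stratum_type == "state",
                                   .data$stratum_value, "ALL")
    )
  out <- mapped |>
    dplyr::inner_join(
      benchmark |>
        dplyr::rename(registry_aci = "aci"),
      by = dplyr::join_by(x$site == y$site, x$bench_sex == y$sex,
                          x$bench_state == y$state)
    ) |>
    dplyr::filter(.data$registry_aci > 0) |>
    dplyr::transmute(
      .data$site, .data$algorithm_label, .data$stratum_type,
      .data$stratum_value, claims_aci = .data$aci, .data$registry_aci,
      pct_diff = percent_difference(.data$aci, .data$registry_aci)
    )
  class(out) <- c("benchmark_comparison", class(out))
  out
}
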