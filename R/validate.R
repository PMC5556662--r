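#' Sensitivity and positive predictive value on synthetic ground truth
#'
#' On real, unlinked claims data the misclassification of a case-finding
#' algorithm cannot be measured; on simulated populations the generator's
#' ground-truth labels make it directly computable. A cohort member counts
#' as a true positive when identified and truly incident in the study year
#' (`INCIDENT_2013`), as a false positive when identified with any other
#' label (prevalent, recurrent, suspected-only, incident in another year, or
#' disease free), and as a false negative when truly incident but not
#' identified.
#'
#' @param cases An `incident_cases` tibble (see [identify_incident_cases()]).
#' @param ground_truth Ground-truth tibble from [generate_population()]
#'   (`person_id`, `site`, `true_onset_quarter`, `case_type`).
#' @param cohort A [build_cohort()] result; metrics are computed over cohort
#'   members with site-eligible sex only.
#' @param site A [cancer_site()] or name.
#' @param algorithm_label Grid label selecting the cases to evaluate.
#' @return An object of class `case_validation`: counts `tp`, `fp`, `fn`,
#'   plus `sensitivity = tp / (tp + fn)` and `ppv = tp / (tp + fp)`
#'   (`NA` where the denominator is empty). Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
validation_metrics <- function(cases, ground_truth, cohort, site,
                               algorithm_label) {
  site <- as_cancer_site(site)
  eligible <- tibble::as_tibble(cohort) |>
    dplyr::filter(.data$sex %in% site$eligible_sexes)
  truth <- ground_truth |>
    dplyr::filter(.data$site == !!site$name,
                  .data$person_id %in% eligible$person_id)
  identified <- cases |>
    dplyr::filter(.data$site == !!site$name,
                  .data$algorithm_label == !!algorithm_label,
                  .data$person_id %in% eligible$person_id)

  true_pos_ids <- truth$person_id[truth$case_type == "INCIDENT_2013"]
  tp <- sum(identified$person_id %in% true_pos_ids)
  fp <- nrow(identified) - tp
  fn <- sum(!true_pos_ids %in% identified$person_id)

  structure(
    list(site = site$name, algorithm_label = algorithm_label,
         n_eligible = nrow(eligible), tp = tp, fp = fp, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_),
    class = "case_validation"
  )
}

#' @export
print.case_validation <- function(x, ...) {
  cat(sprintf(
    "<case_validation> %s / %s over %d eligible persons\n  TP %d  FP %d  FN %d\n  sensitivity %s  PPV %s\n",
    x$site, x$algorithm_label, x$n_eligible, x$tp, x$fp, x$fn,
    format_metric(x$sensitivity), format_metric(x$ppv)
  ))
  invisible(x)
}

format_metric <- function(v) {
  if (is.na(v)) "undefined" else sprintf("%.3f", v)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname validation_metrics
#' @param x A `case_validation` object.
#' @param ... Unused.
#' @export
tidy.case_validation <- function(x, ...) {
  tibble::tibble(
    site = x$site, algorithm_label = x$algorithm_label,
    metric = c("tp", "fp", "fn", "sensitivity", "ppv"),
    value = c(x$tp, x$fp, x$fn, x$sensitivity, x$ppv)
  )
}

#' @rdname validation_metrics
#' @export
glance.case_validation <- function(x, ...) {
  tibble::tibble(
    site = x$site, algorithm_label = x$algorithm_label,
    n_eligible = x$n_eligible, tp = x$tp, fp = x$fp, fn = x$fn,
    sensitivity = x$sensitivity, ppv = x$ppv
  )
}
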