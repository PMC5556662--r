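#' Case-finding algorithm specification
#'
#' One cell of the algorithm grid. An algorithm is parameterised by the
#' lookback (washout) length in years, the confirmation-period length in
#' quarters, and the admissible confirmatory events:
#'
#' * `lookback_years` (L, 1..7): quarters `[index - 4L, index - 1]` must be
#'   free of any qualifying diagnosis of the site.
#' * `confirmation_quarters` (C, 0/1/4): a confirmatory event must fall in
#'   the window after the index quarter; `C = 0` means no confirmation is
#'   required.
#' * `allow_death_confirm`: death in `[index, index + C]` counts as a
#'   confirmatory event (the `-ed` variants switch this off).
#' * `require_surgery_confirm`: a site-specific surgery in
#'   `[index, index + C]` is the required (necessary and sufficient)
#'   confirmatory event (the `-su` variants; not applicable to prostate).
#'
#' @param label Short label such as `"L7-C1"`.
#' @param lookback_years Integer 1..7.
#' @param confirmation_quarters Integer >= 0.
#' @param allow_death_confirm Logical.
#' @param require_surgery_confirm Logical.
#' @return A list of class `algorithm_spec`.
#' @examples
#' algorithm_spec("L1-C1", 1, 1)  # the baseline algorithm
#' @export
algorithm_spec <- function(label, lookback_years, confirmation_quarters,
                           allow_death_confirm = TRUE,
                           require_surgery_confirm = FALSE) {
  lookback_years <- as.integer(lookback_years)
  confirmation_quarters <- as.integer(confirmation_quarters)
  stopifnot(lookback_years >= 1, confirmation_quarters >= 0)
  require_confirmation <- confirmation_quarters > 0
  if (require_surgery_confirm && !require_confirmation) {
    rlang::abort("surgery confirmation needs a confirmation period (C > 0)",
                 class = "oncoclaims_config_error")
  }
  structure(
    list(label = label,
         lookback_years = lookback_years,
         confirmation_quarters = confirmation_quarters,
         require_confirmation = require_confirmation,
         allow_death_confirm = allow_death_confirm,
         require_surgery_confirm = require_surgery_confirm),
    class = "algorithm_spec"
  )
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat(sprintf(
    "<algorithm_spec> %s: lookback %dy, confirmation %dq%s%s%s\n",
    x$label, x$lookback_years, x$confirmation_quarters,
    if (!x$require_confirmation) " (no confirmatory event required)" else "",
    if (x$require_confirmation && !x$allow_death_confirm)
      ", death excluded" else "",
    if (x$require_surgery_confirm) ", surgery required" else ""
  ))
  invisible(x)
}

#' The 15-algorithm grid
#'
#' Enumerates the full grid of case-finding algorithms: seven lookback
#' lengths at a 1-quarter confirmation (L1-C1 ... L7-C1, with L1-C1 the
#' baseline), the 4-quarter confirmation at both extreme lookbacks (L1-C4,
#' L7-C4), no confirmation (L1-C0, L7-C0), death excluded as a confirmatory
#' event (L1-C1-ed, L7-C1-ed) and surgery required as the confirmatory event
#' (L1-C4-su, L7-C4-su).
#'
#' @return A named list of 15 [algorithm_spec()] objects.
#' @examples
#' names(algorithm_grid())
#' @export
algorithm_grid <- function() {
  specs <- c(
    purrr::map(1:7, ~ algorithm_spec(sprintf("L%d-C1", .x), .x, 1L)),
    list(
      algorithm_spec("L1-C4", 1L, 4L),
      algorithm_spec("L7-C4", 7L, 4L),
      algorithm_spec("L1-C0", 1L, 0L),
      algorithm_spec("L7-C0", 7L, 0L),
      algorithm_spec("L1-C1-ed", 1L, 1L, allow_death_confirm = FALSE),
      algorithm_spec("L7-C1-ed", 7L, 1L, allow_death_confirm = FALSE),
      algorithm_spec("L1-C4-su", 1L, 4L, require_surgery_confirm = TRUE),
      algorithm_spec("L7-C4-su", 7L, 4L, require_surgery_confirm = TRUE)
    )
  )
  stats::setNames(specs, purrr::map_chr(specs, "label"))
}

as_algorithm_spec <- function(x) {
  if (inherits(x, "algorithm_spec")) return(x)
  grid <- algorithm_grid()
  if (is.character(x) && length(x) == 1 && x %in% names(grid)) {
    return(grid[[x]])
  }
  rlang::abort(
    sprintf("unknown algorithm '%s' (see algorithm_grid())",
            paste(x, collapse = ",")),
    class = "oncoclaims_config_error"
  )
}
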