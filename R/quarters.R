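#' Calendar quarters on a linear index
#'
#' Outpatient diagnoses in German statutory-health-insurance (SHI) claims are
#' resolved only to the calendar quarter, so the case-finding algorithms in
#' this package operate on a linear quarter index
#' `index = 4 * year + (quarter - 1)`. Consecutive quarters differ by exactly
#' 1, which makes lookback and confirmation windows plain integer arithmetic.
#'
#' Quarters are serialised as `"YYYYQn"` (e.g. `"2013Q2"`): unambiguous and
#' sortable as text.
#'
#' @param year Integer calendar year(s).
#' @param q Integer quarter-of-year in 1..4.
#' @return `quarter_index()` returns an integer vector; `quarter_year()` and
#'   `quarter_of_year()` invert it; `format_quarter()` and `parse_quarter()`
#'   convert to and from the `"YYYYQn"` form.
#' @examples
#' quarter_index(2013, 1) - quarter_index(2012, 4)  # consecutive quarters
#' format_quarter(quarter_index(2006, 3))
#' @export
quarter_index <- function(year, q) {
  stopifnot(all(q %in% 1:4 | is.na(q)))
  as.integer(4L * as.integer(year) + (as.integer(q) - 1L))
}

#' @rdname quarter_index
#' @param qi Integer quarter index as returned by `quarter_index()`.
#' @export
quarter_year <- function(qi) as.integer(qi %/% 4L)

#' @rdname quarter_index
#' @export
quarter_of_year <- function(qi) as.integer(qi %% 4L + 1L)

#' @rdname quarter_index
#' @export
format_quarter <- function(qi) {
  out <- sprintf("%04dQ%d", quarter_year(qi), quarter_of_year(qi))
  out[is.na(qi)] <- NA_character_
  out
}

#' @rdname quarter_index
#' @param x Character vector of `"YYYYQn"` strings.
#' @export
parse_quarter <- function(x) {
  ok <- is.na(x) | grepl("^[0-9]{4}Q[1-4]$", x)
  if (!all(ok)) {
    rlang::abort(
      sprintf(
        "malformed quarter string(s): %s",
        paste(utils::head(unique(x[!ok]), 5L), collapse = ", ")
      ),
      class = "oncoclaims_input_error"
    )
  }
  quarter_index(substr(x, 1, 4), substr(x, 6, 6))
}

#' Map a calendar date onto the quarterly grid
#'
#' Dated events (inpatient discharges, procedures, deaths) are aligned with
#' the quarter-resolved outpatient record by the quarter containing the date.
#'
#' @param d A `Date` vector, or character in ISO 8601 (`YYYY-MM-DD`).
#' @return Integer quarter index (see [quarter_index()]).
#' @examples
#' format_quarter(date_to_quarter(as.Date("2006-07-15")))  # "2006Q3"
#' @export
date_to_quarter <- function(d) {
  if (is.character(d)) d <- parse_iso_date(d)
  if (!inherits(d, "Date")) {
    rlang::abort("`d` must be a Date or an ISO 8601 date string",
                 class = "oncoclaims_input_error")
  }
  quarter_index(lubridate::year(d), lubridate::quarter(d))
}

# Strict ISO-8601 date parsing; anything else is an input error.
parse_iso_date <- function(x) {
  bad_shape <- !is.na(x) & !grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  d <- as.Date(rep(NA_character_, length(x)))
  d[!bad_shape] <- as.Date(x[!bad_shape], format = "%Y-%m-%d")
  failed <- bad_shape | (!is.na(x) & is.na(d))
  if (any(failed)) {
    rlang::abort(
      sprintf("malformed date(s): %s",
              paste(utils::head(unique(x[failed]), 5L), collapse = ", ")),
      class = "oncoclaims_input_error"
    )
  }
  d
}

# Reporting-layer rounding: half away from zero, as printed incidence tables
# use. All internal comparisons stay unrounded.
round_half_out <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
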