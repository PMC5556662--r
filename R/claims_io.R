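#' Read and validate a set of claims tables
#'
#' Claims data are exchanged as five comma-separated UTF-8 tables with header
#' rows:
#'
#' * `persons.csv` — `person_id, sex, birth_year, state, death_date`
#' * `spells.csv` — `person_id, start, end` (closed intervals of covered days)
#' * `outpatient_dx.csv` — `person_id, quarter, icd_code, certainty`
#' * `inpatient_dx.csv` — `person_id, admission_date, discharge_date,
#'   icd_code, dx_type`
#' * `procedures.csv` — `person_id, date, proc_class`
#'
#' Dates are ISO 8601 (`YYYY-MM-DD`), quarters `"YYYYQn"`. Outpatient
#' diagnoses carry the mandatory German diagnostic-certainty marker:
#' G (certain), V (suspected), Z (status post) or A (excluded). Inpatient
#' diagnoses are flagged `MAIN_DISCHARGE` (discharge diagnosis reflecting the
#' reason for hospitalisation) or `ANCILLARY`. Procedures carry an abstract
#' `proc_class` rather than raw OPS/EBM codes; map real procedure codes to
#' these classes upstream when working with real data.
#'
#' A missing column raises a schema error. Rows violating a field invariant
#' (unknown certainty marker, unparseable date, admission after discharge,
#' a spell overlapping an earlier spell of the same person, ...) are dropped;
#' their counts are reported in a message and returned in the
#' `rejected_rows` attribute of the result.
#'
#' @param dir Directory containing the five tables under their standard
#'   names. Alternatively pass `paths`, a named list/vector with elements
#'   `persons`, `spells`, `outpatient`, `inpatient`, `procedures`.
#' @param paths Optional named paths overriding `dir`.
#' @param quiet Suppress the rejected-row message.
#' @return A list of class `claims_tables` with tibbles `persons`, `spells`,
#'   `outpatient`, `inpatient`, `procedures`; typed columns (`Date` dates,
#'   integer birth years, `"YYYYQn"` quarters kept as character).
#' @seealso [write_claims_tables()] for the inverse; [generate_population()]
#'   to simulate a population in this shape.
#' @export
read_claims_tables <- function(dir = NULL, paths = NULL, quiet = FALSE) {
  if (is.null(paths)) {
    if (is.null(dir)) {
      rlang::abort("supply `dir` or `paths`", class = "oncoclaims_input_error")
    }
    paths <- list(
      persons = file.path(dir, "persons.csv"),
      spells = file.path(dir, "spells.csv"),
      outpatient = file.path(dir, "outpatient_dx.csv"),
      inpatient = file.path(dir, "inpatient_dx.csv"),
      procedures = file.path(dir, "procedures.csv")
    )
  }
  paths <- as.list(paths)
  missing_tab <- setdiff(
    c("persons", "spells", "outpatient", "inpatient", "procedures"),
    names(paths)
  )
  if (length(missing_tab)) {
    rlang::abort(paste("missing table path(s):",
                       paste(missing_tab, collapse = ", ")),
                 class = "oncoclaims_schema_error")
  }

  raw <- purrr::map(paths, read_raw_table)
  check_schema(raw)
  validated <- validate_claims_tables(raw)
  if (!quiet) {
    nrej <- purrr::map_int(validated$rejected, nrow)
    if (sum(nrej) > 0) {
      message(
        "rejected rows: ",
        paste(sprintf("%s=%d", names(nrej)[nrej > 0], nrej[nrej > 0]),
              collapse = ", ")
      )
    }
  }
  structure(validated$tables,
            rejected_rows = validated$rejected,
            class = c("claims_tables", "list"))
}

claims_schemas <- function() {
  list(
    persons = c("person_id", "sex", "birth_year", "state", "death_date"),
    spells = c("person_id", "start", "end"),
    outpatient = c("person_id", "quarter", "icd_code", "certainty"),
    inpatient = c("person_id", "admission_date", "discharge_date",
                  "icd_code", "dx_type"),
    procedures = c("person_id", "date", "proc_class")
  )
}

read_raw_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste("file not found:", path),
                 class = "oncoclaims_schema_error")
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = c("", "NA"))
}

check_schema <- function(raw) {
  schemas <- claims_schemas()
  for (nm in names(schemas)) {
    missing_col <- setdiff(schemas[[nm]], names(raw[[nm]]))
    if (length(missing_col)) {
      rlang::abort(
        sprintf("table '%s' is missing column(s): %s", nm,
                paste(missing_col, collapse = ", ")),
        class = "oncoclaims_schema_error"
      )
    }
  }
  invisible(TRUE)
}

# Lenient date parse: returns NA where unparseable instead of aborting, so
# offending rows can be rejected individually.
parse_date_or_na <- function(x) {
  ok <- !is.na(x) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  d <- as.Date(rep(NA_character_, length(x)))
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  d
}

validate_claims_tables <- function(raw) {
  rejected <- list()

  p <- raw$persons
  p_bad <- is.na(p$person_id) | p$person_id == "" | duplicated(p$person_id) |
    !(p$sex %in% c("F", "M", "MISSING")) |
    !(is.na(p$birth_year) | grepl("^[0-9]{4}$", p$birth_year)) |
    !(p$state %in% c(german_states(), "FOREIGN", "MISSING")) |
    !(is.na(p$death_date) | grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", p$death_date))
  rejected$persons <- p[p_bad, , drop = FALSE]
  persons <- p[!p_bad, , drop = FALSE] |>
    dplyr::mutate(
      birth_year = suppressWarnings(as.integer(.data$birth_year)),
      death_date = parse_date_or_na(.data$death_date)
    ) |>
    tibble::as_tibble()

  s <- raw$spells |>
    dplyr::mutate(start = parse_date_or_na(.data$start),
                  end = parse_date_or_na(.data$end))
  s_bad <- is.na(s$person_id) | is.na(s$start) | is.na(s$end) |
    s$start > s$end | !(s$person_id %in% persons$person_id)
  # person-level invariant: spells sorted and pairwise disjoint; a spell
  # overlapping the previous accepted spell of the same person is rejected
  s_ok <- s[!s_bad, , drop = FALSE] |>
    dplyr::arrange(.data$person_id, .data$start, .data$end) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(.overlap = dplyr::row_number() > 1 &
                    .data$start <= dplyr::lag(cummax_date(.data$end))) |>
    dplyr::ungroup()
  rejected$spells <- dplyr::bind_rows(
    raw$spells[s_bad, , drop = FALSE],
    s_ok[s_ok$.overlap, c("person_id"), drop = FALSE]
  )
  spells <- s_ok |>
    dplyr::filter(!.data$.overlap) |>
    dplyr::select("person_id", "start", "end") |>
    tibble::as_tibble()

  o <- raw$outpatient
  o_bad <- is.na(o$person_id) | !(o$certainty %in% certainty_levels()) |
    is.na(o$icd_code) | o$icd_code == "" |
    !(!is.na(o$quarter) & grepl("^[0-9]{4}Q[1-4]$", o$quarter))
  rejected$outpatient <- o[o_bad, , drop = FALSE]
  outpatient <- tibble::as_tibble(o[!o_bad, , drop = FALSE])

  i <- raw$inpatient |>
    dplyr::mutate(.adm = parse_date_or_na(.data$admission_date),
                  .dis = parse_date_or_na(.data$discharge_date))
  i_bad <- is.na(i$person_id) | is.na(i$.adm) | is.na(i$.dis) |
    i$.adm > i$.dis | !(i$dx_type %in% dx_type_levels()) |
    is.na(i$icd_code) | i$icd_code == ""
  rejected$inpatient <- raw$inpatient[i_bad, , drop = FALSE]
  inpatient <- i[!i_bad, , drop = FALSE] |>
    dplyr::transmute(.data$person_id, admission_date = .data$.adm,
                     discharge_date = .data$.dis, .data$icd_code,
                     .data$dx_type) |>
    tibble::as_tibble()

  pr <- raw$procedures |>
    dplyr::mutate(.date = parse_date_or_na(.data$date))
  pr_bad <- is.na(pr$person_id) | is.na(pr$.date) |
    !(pr$proc_class %in% proc_class_levels())
  rejected$procedures <- raw$procedures[pr_bad, , drop = FALSE]
  procedures <- pr[!pr_bad, , drop = FALSE] |>
    dplyr::transmute(.data$person_id, date = .data$.date, .data$proc_class) |>
    tibble::as_tibble()

  list(
    tables = list(persons = persons, spells = spells, outpatient = outpatient,
                  inpatient = inpatient, procedures = procedures),
    rejected = rejected
  )
}

# running max for Date vectors (cummax drops the class)
cummax_date <- function(x) as.Date(cummax(as.integer(x)), origin = "1970-01-01")

#' Write claims tables to a directory
#'
#' Serialises a `claims_tables` list (as returned by [read_claims_tables()]
#' or [generate_population()]) back to the five standard CSV files. A
#' write-then-read round trip reproduces the tables exactly.
#'
#' @param claims A `claims_tables` list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims_tables <- function(claims, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(persons = "persons.csv", spells = "spells.csv",
             outpatient = "outpatient_dx.csv", inpatient = "inpatient_dx.csv",
             procedures = "procedures.csv")
  if (!is.null(claims$ground_truth)) {
    files <- c(files, ground_truth = "ground_truth.csv")
  }
  for (nm in names(files)) {
    tab <- claims[[nm]]
    date_cols <- names(tab)[purrr::map_lgl(tab, inherits, "Date")]
    for (dc in date_cols) tab[[dc]] <- format(tab[[dc]], "%Y-%m-%d")
    readr::write_csv(tab, file.path(dir, files[[nm]]), na = "", progress = FALSE)
  }
  invisible(dir)
}
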