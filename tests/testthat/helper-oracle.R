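# Brute-force reference implementation of the case definition, written as
# plain per-person loops over the quarter grid, independent of the
# vectorised engine. Used to cross-check identify_incident_cases() on small
# random populations.

oracle_qi <- function(year, q) 4L * year + (q - 1L)

oracle_date_qi <- function(d) {
  d <- as.Date(d)
  oracle_qi(as.integer(format(d, "%Y")),
            (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L)
}

oracle_icd_match <- function(code, prefixes) {
  code <- toupper(gsub(".", "", code, fixed = TRUE))
  substr(code, 1, 3) %in% prefixes
}

# all site events of one person as (qi, index_ok) pairs
oracle_person_events <- function(claims, pid, prefixes) {
  evs <- list()
  ot <- claims$outpatient[claims$outpatient$person_id == pid, ]
  for (i in seq_len(nrow(ot))) {
    if (!oracle_icd_match(ot$icd_code[i], prefixes)) next
    cert <- ot$certainty[i]
    if (cert %in% c("V", "A")) next
    y <- as.integer(substr(ot$quarter[i], 1, 4))
    q <- as.integer(substr(ot$quarter[i], 6, 6))
    evs[[length(evs) + 1]] <- list(qi = oracle_qi(y, q),
                                   index_ok = cert == "G")
  }
  it <- claims$inpatient[claims$inpatient$person_id == pid, ]
  for (i in seq_len(nrow(it))) {
    if (!oracle_icd_match(it$icd_code[i], prefixes)) next
    evs[[length(evs) + 1]] <- list(
      qi = oracle_date_qi(it$discharge_date[i]),
      index_ok = it$dx_type[i] == "MAIN_DISCHARGE"
    )
  }
  evs
}

oracle_identify <- function(claims, cohort, site_name, spec,
                            study_year = 2013) {
  site <- cancer_site(site_name)
  spec <- if (is.character(spec)) algorithm_grid()[[spec]] else spec
  found <- character(0)
  for (pid in cohort$person_id) {
    sex <- cohort$sex[cohort$person_id == pid]
    if (!sex %in% site$eligible_sexes) next
    evs <- oracle_person_events(claims, pid, site$icd_prefixes)
    if (!length(evs)) next

    # earliest index-qualifying quarter of the study year
    index_qi <- Inf
    for (e in evs) {
      if (e$index_ok && e$qi >= oracle_qi(study_year, 1L) &&
          e$qi <= oracle_qi(study_year, 4L) && e$qi < index_qi) {
        index_qi <- e$qi
      }
    }
    if (!is.finite(index_qi)) next

    # washout: any qualifying event in the 4L preceding quarters kills it
    clean <- TRUE
    for (e in evs) {
      if (e$qi >= index_qi - 4L * spec$lookback_years &&
          e$qi <= index_qi - 1L) clean <- FALSE
    }
    if (!clean) next

    # confirmatory event
    ok <- FALSE
    if (!spec$require_confirmation) {
      ok <- TRUE
    } else if (spec$require_surgery_confirm) {
      pr <- claims$procedures[claims$procedures$person_id == pid, ]
      for (i in seq_len(nrow(pr))) {
        if (pr$proc_class[i] %in% site$surgery_classes) {
          pq <- oracle_date_qi(pr$date[i])
          if (pq >= index_qi && pq <= index_qi + spec$confirmation_quarters) {
            ok <- TRUE
          }
        }
      }
    } else {
      for (e in evs) {
        if (e$qi >= index_qi + 1L &&
            e$qi <= index_qi + spec$confirmation_quarters) ok <- TRUE
      }
      if (!ok && spec$allow_death_confirm) {
        dd <- claims$persons$death_date[claims$persons$person_id == pid]
        if (length(dd) == 1 && !is.na(dd)) {
          dq <- oracle_date_qi(dd)
          if (dq >= index_qi && dq <= index_qi + spec$confirmation_quarters) {
            ok <- TRUE
          }
        }
      }
    }
    if (ok) found <- c(found, pid)
  }
  sort(found)
}
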