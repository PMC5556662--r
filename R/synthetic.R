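#' Simulation configuration for a synthetic insured population
#'
#' Defines the population, enrollment, disease and coding processes of the
#' claims simulator. Defaults describe a statutory-health-insurance-like
#' population observed over 2006--2014 with an adult-skewed age pyramid,
#' realistic federal-state mix, small rates of missing demographic
#' information and foreign residence, occasional enrollment gaps, and a
#' per-site cancer model with prevalent-at-start disease, recurrence,
#' watchful waiting (prostate), suspected-only coding noise and
#' post-treatment status-post coding -- the structural features that
#' lookback and confirmation rules exploit.
#'
#' All disease and coding parameters are probabilities (per quarter where
#' noted). Site models can be partially overridden through `disease`; any
#' field not supplied keeps its default.
#'
#' @param n_persons Number of insured persons.
#' @param seed RNG seed giving bit-identical output.
#' @param first_year,last_year Calendar span of the data (default
#'   2006--2014).
#' @param study_year Year whose incident cases are of interest (2013).
#' @param p_female Probability of female sex.
#' @param p_sex_missing,p_birth_year_missing Rates of missing demographic
#'   fields.
#' @param age_distribution Named numeric vector of probabilities over the
#'   18 five-year age bands (age in the study year); must sum to 1.
#' @param state_probs Named probabilities over the 16 federal states
#'   (summing to 1); scaled down by the foreign/missing rates.
#' @param p_state_foreign,p_state_missing Rates of foreign residence and
#'   missing state.
#' @param enrollment List: `p_late_entry` (enrollment after the span
#'   start), `p_early_exit` (disenrollment before the span end), `p_gap`
#'   (probability of one coverage gap), `gap_mean_days` (mean gap length;
#'   geometric, so roughly a quarter of gaps exceed the 28-day continuity
#'   limit at the default mean of 22).
#' @param mortality List `annual_base`, `annual_growth`: background
#'   mortality hazard `annual_base * exp(annual_growth * age)` per year.
#' @param disease Named list of per-site overrides; see
#'   [default_disease_model()] for the fields.
#' @param benign_dx_mean Mean number of unrelated (non-cancer) outpatient
#'   diagnoses per person over the span.
#' @return A validated list of class `sim_config`.
#' @seealso [generate_population()], [sim_config_perfect()],
#'   [read_sim_config()]
#' @export
sim_config <- function(n_persons = 50000,
                       seed = 20130101,
                       first_year = 2006, last_year = 2014,
                       study_year = 2013,
                       p_female = 0.605,
                       p_sex_missing = 2.6e-6,
                       p_birth_year_missing = 6.9e-5,
                       age_distribution = default_age_distribution(),
                       state_probs = default_state_probs(),
                       p_state_foreign = 0.0028,
                       p_state_missing = 0.0045,
                       enrollment = list(),
                       mortality = list(),
                       disease = list(),
                       benign_dx_mean = 2) {
  enrollment <- utils::modifyList(
    list(p_late_entry = 0.08, p_early_exit = 0.03, p_gap = 0.10,
         gap_mean_days = 22),
    enrollment
  )
  mortality <- utils::modifyList(
    list(annual_base = 6e-5, annual_growth = 0.083),
    mortality
  )
  disease_full <- purrr::map(
    stats::setNames(cancer_sites(), cancer_sites()),
    function(s) {
      dm <- utils::modifyList(default_disease_model(s),
                              disease[[s]] %||% list())
      dm$hazard_q <- align_named(dm$hazard_q, age_band_labels())
      dm$p_prevalent <- align_named(dm$p_prevalent, age_band_labels())
      dm
    }
  )
  age_distribution <- align_named(age_distribution, age_band_labels())
  state_probs <- align_named(state_probs, german_states())
  cfg <- structure(
    list(n_persons = as.integer(n_persons), seed = as.integer(seed),
         first_year = as.integer(first_year),
         last_year = as.integer(last_year),
         study_year = as.integer(study_year),
         p_female = p_female, p_sex_missing = p_sex_missing,
         p_birth_year_missing = p_birth_year_missing,
         age_distribution = age_distribution,
         state_probs = state_probs,
         p_state_foreign = p_state_foreign,
         p_state_missing = p_state_missing,
         enrollment = enrollment, mortality = mortality,
         disease = disease_full, benign_dx_mean = benign_dx_mean),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_age_distribution <- function() {
  stats::setNames(
    c(0.030, 0.032, 0.034, 0.038, 0.045, 0.050, 0.052, 0.055, 0.062,
      0.075, 0.085, 0.082, 0.070, 0.062, 0.068, 0.075, 0.050, 0.035),
    age_band_labels()
  )
}

#' @rdname sim_config
#' @export
default_state_probs <- function() {
  stats::setNames(
    c(0.131, 0.157, 0.043, 0.030, 0.008, 0.022, 0.075, 0.020,
      0.096, 0.219, 0.049, 0.012, 0.050, 0.027, 0.035, 0.026),
    german_states()
  )
}

#' Default per-site disease and coding model
#'
#' Fields (probabilities per quarter unless stated):
#' * `hazard_q`: onset hazard by 5-year age band (18 values).
#' * `p_prevalent`: probability of prevalent disease at the span start, by
#'   age band.
#' * `p_recurrence`, `recurrence_mean_latency_q`: probability that a
#'   prevalent case recurs during the span, and the mean latency in
#'   quarters from the span start.
#' * `fatality_q`: excess case-fatality hazard after onset/recurrence.
#' * `coding`: list with `p_index_coded` (index quarter carries a claims
#'   diagnosis), `p_index_inpatient` (the index record is a main discharge
#'   diagnosis rather than a G-coded outpatient one), `p_followup_g` and
#'   `followup_quarters` (certain-coded follow-up visits), `p_ancillary`
#'   (an ancillary hospital diagnosis during follow-up),
#'   `p_z_post`/`z_quarters` (status-post coding after treatment),
#'   `p_history_miscode` (a spurious certain-coded diagnosis some quarters
#'   before true onset, e.g. workup coded as certain),
#'   `p_g_prevalent`/`p_z_prevalent` (surveillance coding of prevalent
#'   disease), `p_suspected_only` (per-person probability that a
#'   disease-free person receives a single suspected (V) diagnosis),
#'   `p_excluded_dx` (an excluded (A) diagnosis among disease-free
#'   persons), `p_surgery`, `surgery_max_delay_days`,
#'   `recurrence_surgery_factor`, and for prostate
#'   `watchful_fraction`/`watchful_p_followup` (watchful-waiting cases
#'   with sparse follow-up coding).
#'
#' @param site Site name.
#' @return A list of model parameters.
#' @export
default_disease_model <- function(site) {
  site <- toupper(site)
  hz <- switch(site,
    BREAST = c(0, 0, 0, 0, 2e-5, 5e-5, 1e-4, 1.8e-4, 3.0e-4, 4.5e-4,
               5.5e-4, 6.0e-4, 7.0e-4, 7.5e-4, 7.5e-4, 7.0e-4, 6.5e-4,
               5.5e-4),
    PROSTATE = c(0, 0, 0, 0, 0, 0, 0, 0, 5e-5, 1.5e-4, 3.5e-4, 6e-4,
                 9e-4, 1.2e-3, 1.3e-3, 1.2e-3, 1.0e-3, 7e-4),
    COLORECTAL = c(0, 0, 0, 0, 0, 0, 2e-5, 3e-5, 5e-5, 9e-5, 1.5e-4,
                   2.2e-4, 3.2e-4, 4.5e-4, 6e-4, 7.5e-4, 9e-4, 1e-3)
  )
  names(hz) <- age_band_labels()
  coding <- list(
    p_index_coded = 0.92,
    p_index_inpatient = 0.30,
    p_followup_g = 0.85,
    followup_quarters = 3L,
    p_ancillary = 0.08,
    p_z_post = 0.25,
    z_quarters = 12L,
    p_history_miscode = 0.08,
    p_g_prevalent = 0.03,
    p_z_prevalent = 0.15,
    p_suspected_only = switch(site, BREAST = 0.010, PROSTATE = 0.010,
                              COLORECTAL = 0.008),
    p_excluded_dx = 0.002,
    p_surgery = switch(site, BREAST = 0.70, PROSTATE = 0, COLORECTAL = 0.65),
    surgery_max_delay_days = 120L,
    recurrence_surgery_factor = 0.5,
    watchful_fraction = if (site == "PROSTATE") 0.25 else 0,
    watchful_p_followup = 0.20
  )
  list(
    hazard_q = hz,
    p_prevalent = pmin(hz * 40, 0.25),
    p_recurrence = 0.25,
    recurrence_mean_latency_q = 16,
    fatality_q = switch(site, BREAST = 0.012, PROSTATE = 0.010,
                        COLORECTAL = 0.035),
    coding = coding
  )
}

#' A perfect-coding, noise-free configuration
#'
#' Convenience preset for calibration and recovery checks: a flat quarterly
#' onset hazard per site across all ages, every onset coded in its quarter
#' and in the following quarter, and no prevalence, recurrence, suspected
#' coding, mortality, missingness or enrollment gaps. Under this
#' configuration the fraction of persons truly incident in the study year
#' is governed by the closed form `1 - (1 - h)^4` (up to survival of the
#' pre-study quarters), and a long-lookback algorithm should recover the
#' configured incidence exactly up to sampling error.
#'
#' @param n_persons,seed As in [sim_config()].
#' @param hazard_q Named per-quarter onset hazards, one per site.
#' @return A `sim_config`.
#' @export
sim_config_perfect <- function(n_persons = 50000, seed = 20130101,
                               hazard_q = c(BREAST = 6e-4, PROSTATE = 6e-4,
                                            COLORECTAL = 4e-4)) {
  flat <- function(h) stats::setNames(rep(h, 18), age_band_labels())
  perfect_coding <- list(
    p_index_coded = 1, p_index_inpatient = 0, p_followup_g = 1,
    followup_quarters = 1L, p_ancillary = 0, p_z_post = 0, z_quarters = 1L,
    p_history_miscode = 0, p_g_prevalent = 0, p_z_prevalent = 0,
    p_suspected_only = 0, p_excluded_dx = 0, p_surgery = 0,
    surgery_max_delay_days = 0L, recurrence_surgery_factor = 0,
    watchful_fraction = 0, watchful_p_followup = 0
  )
  site_model <- function(h) {
    list(hazard_q = flat(h), p_prevalent = flat(0), p_recurrence = 0,
         recurrence_mean_latency_q = 16, fatality_q = 0,
         coding = perfect_coding)
  }
  sim_config(
    n_persons = n_persons, seed = seed,
    p_sex_missing = 0, p_birth_year_missing = 0,
    p_state_foreign = 0, p_state_missing = 0,
    enrollment = list(p_late_entry = 0, p_early_exit = 0, p_gap = 0,
                      gap_mean_days = 22),
    mortality = list(annual_base = 0, annual_growth = 0),
    disease = purrr::map(
      stats::setNames(cancer_sites(), cancer_sites()),
      ~ site_model(hazard_q[[.x]])
    ),
    benign_dx_mean = 0
  )
}

validate_sim_config <- function(cfg) {
  err <- function(msg) rlang::abort(msg, class = "oncoclaims_config_error")
  prob_fields <- c(cfg$p_female, cfg$p_sex_missing, cfg$p_birth_year_missing,
                   cfg$p_state_foreign, cfg$p_state_missing,
                   unlist(cfg$enrollment[c("p_late_entry", "p_early_exit",
                                           "p_gap")]))
  if (any(prob_fields < 0 | prob_fields > 1)) {
    err("probabilities must lie in [0, 1]")
  }
  if (cfg$n_persons < 1) err("n_persons must be positive")
  if (cfg$first_year > cfg$study_year || cfg$study_year > cfg$last_year) {
    err("study_year must lie within [first_year, last_year]")
  }
  if (abs(sum(cfg$age_distribution) - 1) > 1e-6) {
    err("age_distribution must sum to 1")
  }
  if (abs(sum(cfg$state_probs) - 1) > 1e-6) {
    err("state_probs must sum to 1")
  }
  for (s in names(cfg$disease)) {
    dm <- cfg$disease[[s]]
    if (length(dm$hazard_q) != 18 || any(dm$hazard_q < 0 | dm$hazard_q > 1)) {
      err(sprintf("%s: hazard_q must be 18 probabilities", s))
    }
    if (any(dm$p_prevalent < 0 | dm$p_prevalent > 1)) {
      err(sprintf("%s: p_prevalent out of [0, 1]", s))
    }
    cp <- unlist(dm$coding[c("p_index_coded", "p_index_inpatient",
                             "p_followup_g", "p_ancillary", "p_z_post",
                             "p_history_miscode", "p_g_prevalent",
                             "p_z_prevalent", "p_suspected_only",
                             "p_excluded_dx", "p_surgery",
                             "watchful_fraction", "watchful_p_followup")])
    if (any(cp < 0 | cp > 1)) {
      err(sprintf("%s: coding probabilities out of [0, 1]", s))
    }
  }
  cfg
}

#' Read or write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(sim_config)))]
  if (!is.null(args$age_distribution)) {
    args$age_distribution <- unlist(args$age_distribution)
  }
  if (!is.null(args$state_probs)) args$state_probs <- unlist(args$state_probs)
  if (!is.null(args$disease)) {
    args$disease <- purrr::map(args$disease, function(dm) {
      if (!is.null(dm$hazard_q)) dm$hazard_q <- unlist(dm$hazard_q)
      if (!is.null(dm$p_prevalent)) dm$p_prevalent <- unlist(dm$p_prevalent)
      dm
    })
  }
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @param config A `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  # named vectors become YAML maps so band/state labels survive on disk
  as_mapped <- function(x) {
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    if (is.list(x)) return(purrr::map(x, as_mapped))
    x
  }
  yaml::write_yaml(as_mapped(unclass(config)), path)
  invisible(path)
}

# align a vector to reference names: reorder when fully named, otherwise
# assign names positionally (requires the reference length)
align_named <- function(x, ref) {
  if (length(x) != length(ref)) {
    rlang::abort(sprintf("expected %d values, got %d", length(ref),
                         length(x)),
                 class = "oncoclaims_config_error")
  }
  if (!is.null(names(x)) && setequal(names(x), ref)) return(x[ref])
  stats::setNames(x, ref)
}

# geometric draw tolerating p = 0 (never) and p = 1 (immediately)
safe_rgeom <- function(n, p) {
  p <- rep_len(p, n)
  out <- rep(Inf, n)
  pos <- p > 0
  if (any(pos)) out[pos] <- stats::rgeom(sum(pos), pmin(p[pos], 1))
  out
}

random_day_in_quarter <- function(qi) {
  y <- quarter_year(qi)
  q <- quarter_of_year(qi)
  q_start <- lubridate::make_date(y, 3L * (q - 1L) + 1L, 1L)
  next_q <- lubridate::make_date(y + (q == 4L),
                                 ifelse(q == 4L, 1L, 3L * q + 1L), 1L)
  q_start + floor(stats::runif(length(qi)) * as.integer(next_q - q_start))
}

#' Generate a synthetic insured population with ground truth
#'
#' Simulates persons, insurance spells, outpatient and inpatient diagnoses,
#' procedures and deaths under a [sim_config()], together with a
#' ground-truth label per person and site. The generative order is: ground
#' truth first (prevalence, onset, recurrence, death), then the coding
#' process layered on top -- so labels are independent of how well the
#' disease happens to be coded, which is exactly what makes
#' sensitivity/PPV evaluation of the case-finding algorithms meaningful.
#'
#' Disease is simulated on the quarterly grid; dated events (inpatient
#' stays, surgeries, deaths) receive a uniformly random date within their
#' quarter. No diagnosis is generated before the calendar year of a
#' person's first insurance spell or after the death quarter. Output is
#' bit-identical under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list of class `claims_tables` with `persons`, `spells`,
#'   `outpatient`, `inpatient`, `procedures` and additionally
#'   `ground_truth` (`person_id`, `site`, `true_onset_quarter`,
#'   `case_type` in `INCIDENT_2013`, `INCIDENT_OTHER_YEAR`,
#'   `PREVALENT_AT_START`, `RECURRENT`, `SUSPECTED_ONLY`, `NONE`).
#' @export
generate_population <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config")) {
    rlang::abort("`config` must be a sim_config object",
                 class = "oncoclaims_config_error")
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_persons
  span_start_qi <- quarter_index(config$first_year, 1L)
  span_end_qi <- quarter_index(config$last_year, 4L)
  span_start <- lubridate::make_date(config$first_year, 1L, 1L)
  span_end <- lubridate::make_date(config$last_year, 12L, 31L)

  ## --- persons -------------------------------------------------------
  person_id <- sprintf("P%07d", seq_len(n))
  sex_true <- ifelse(stats::runif(n) < config$p_female, "F", "M")
  sex <- ifelse(stats::runif(n) < config$p_sex_missing, "MISSING", sex_true)
  band_idx <- sample.int(18L, n, replace = TRUE,
                         prob = config$age_distribution)
  band_lo <- (band_idx - 1L) * 5L
  band_width <- ifelse(band_idx == 18L, 10L, 5L)
  age <- band_lo + floor(stats::runif(n) * band_width)
  birth_year <- config$study_year - age
  birth_year_obs <- ifelse(stats::runif(n) < config$p_birth_year_missing,
                           NA_integer_, birth_year)
  state_levels <- c(german_states(), "FOREIGN", "MISSING")
  state_p <- c(config$state_probs *
                 (1 - config$p_state_foreign - config$p_state_missing),
               config$p_state_foreign, config$p_state_missing)
  state <- sample(state_levels, n, replace = TRUE, prob = state_p)

  ## --- enrollment ----------------------------------------------------
  enr <- config$enrollment
  late <- stats::runif(n) < enr$p_late_entry
  start <- rep(span_start, n)
  latest_entry <- lubridate::make_date(config$study_year - 1L, 12L, 31L)
  start[late] <- span_start +
    floor(stats::runif(sum(late)) * as.integer(latest_entry - span_start))
  exit <- stats::runif(n) < enr$p_early_exit
  end <- rep(span_end, n)
  exit_span <- pmax(as.integer(span_end - start) - 60L, 1L)
  end[exit] <- (start + 30L +
    floor(stats::runif(n) * exit_span))[exit]

  ## --- background mortality -----------------------------------------
  mu_q <- pmin(config$mortality$annual_base *
                 exp(config$mortality$annual_growth * age), 0.8) / 4
  death_qi <- span_start_qi + safe_rgeom(n, mu_q)

  ## --- disease processes (ground truth first) -----------------------
  # per-site simulation; death_qi is finalised across sites afterwards
  sim_site <- function(site_name) {
    dm <- config$disease[[site_name]]
    site <- cancer_site(site_name)
    elig <- sex %in% site$eligible_sexes  # MISSING sex stays disease free
    prev <- elig & stats::runif(n) < dm$p_prevalent[band_idx]
    # prevalent onset predates the span: uniform over the prior 16 years
    prev_onset <- quarter_index(config$first_year - 1L -
                                  floor(stats::runif(n) * 16),
                                sample.int(4L, n, replace = TRUE))
    rec_try <- prev & stats::runif(n) < dm$p_recurrence
    rec_qi <- span_start_qi +
      safe_rgeom(n, 1 / dm$recurrence_mean_latency_q)
    rec_qi[!rec_try] <- Inf
    onset_qi <- span_start_qi + safe_rgeom(n, dm$hazard_q[band_idx])
    onset_qi[!elig | prev] <- Inf
    onset_qi[onset_qi > span_end_qi] <- Inf
    # excess mortality after onset / recurrence
    dis_death <- rep(Inf, n)
    has_ep <- is.finite(onset_qi) | is.finite(rec_qi)
    ep_start <- pmin(onset_qi, rec_qi)
    dis_death[has_ep] <- ep_start[has_ep] +
      safe_rgeom(sum(has_ep), dm$fatality_q)
    list(prev = prev, prev_onset = prev_onset, rec_qi = rec_qi,
         onset_qi = onset_qi, dis_death = dis_death)
  }
  sites <- cancer_sites()
  st <- purrr::map(stats::setNames(sites, sites), sim_site)

  death_qi <- pmin(death_qi, purrr::reduce(purrr::map(st, "dis_death"), pmin))
  death_qi[death_qi > span_end_qi] <- Inf
  # nobody dies before enrolling
  start_qi <- date_to_quarter(start)
  death_qi <- pmax(death_qi, start_qi)

  # events are observable from the year of the first spell start up to death
  obs_start_qi <- quarter_index(lubridate::year(start), 1L)
  obs_end_qi <- pmin(span_end_qi, death_qi)

  # drop disease events cut off by death from another cause
  for (s in sites) {
    st[[s]]$onset_qi[st[[s]]$onset_qi > death_qi] <- Inf
    st[[s]]$rec_qi[st[[s]]$rec_qi > death_qi] <- Inf
  }

  ## --- coding process ------------------------------------------------
  ev <- new_event_collector()
  for (s in sites) {
    code_site_events(ev, s, config$disease[[s]], st[[s]], person_id, sex,
                     obs_start_qi, obs_end_qi, config)
  }
  code_benign_events(ev, config, person_id, obs_start_qi, obs_end_qi)

  ## --- death dates, spells -------------------------------------------
  death_date <- rep(as.Date(NA), n)
  dead <- is.finite(death_qi)
  if (any(dead)) {
    dd <- random_day_in_quarter(death_qi[dead])
    death_date[dead] <- pmax(dd, start[dead])
  }
  end <- dplyr::if_else(dead & death_date < end, death_date, end)

  spells <- build_spells(person_id, start, end, enr, span_end)

  persons <- tibble::tibble(
    person_id = person_id, sex = sex, birth_year = birth_year_obs,
    state = state, death_date = death_date
  )

  ## --- ground truth --------------------------------------------------
  truth <- purrr::imap(st, function(x, s) {
    dm <- config$disease[[s]]
    v_only <- ev$v_flag[[s]]
    onset_in_study_year <- is.finite(x$onset_qi) &
      x$onset_qi %/% 4 == config$study_year
    case_type <- dplyr::case_when(
      x$prev & is.finite(x$rec_qi) ~ "RECURRENT",
      x$prev ~ "PREVALENT_AT_START",
      onset_in_study_year ~ "INCIDENT_2013",
      is.finite(x$onset_qi) ~ "INCIDENT_OTHER_YEAR",
      v_only ~ "SUSPECTED_ONLY",
      TRUE ~ "NONE"
    )
    onset_fin <- as.integer(ifelse(is.finite(x$onset_qi), x$onset_qi, NA))
    onset <- dplyr::case_when(
      x$prev ~ as.integer(x$prev_onset),
      !is.na(onset_fin) ~ onset_fin,
      TRUE ~ NA_integer_
    )
    tibble::tibble(
      person_id = person_id, site = s,
      true_onset_quarter = format_quarter(onset),
      case_type = case_type
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$person_id, .data$site)

  out <- list(
    persons = persons,
    spells = spells,
    outpatient = collect_outpatient(ev),
    inpatient = collect_inpatient(ev),
    procedures = collect_procedures(ev),
    ground_truth = truth
  )
  structure(out, config = config, class = c("claims_tables", "list"))
}

# mutable collector for event rows built up site by site
new_event_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$out <- list(); env$inp <- list(); env$proc <- list()
  env$v_flag <- list()
  env
}

push <- function(ev, slot, tbl) {
  if (nrow(tbl)) ev[[slot]] <- c(ev[[slot]], list(tbl))
  invisible(ev)
}

collect_outpatient <- function(ev) {
  base <- tibble::tibble(person_id = character(), quarter = character(),
                         icd_code = character(), certainty = character())
  tab <- dplyr::bind_rows(c(list(base), ev$out))
  dplyr::arrange(tab, .data$person_id, .data$quarter, .data$icd_code,
                 .data$certainty)
}

collect_inpatient <- function(ev) {
  base <- tibble::tibble(person_id = character(),
                         admission_date = as.Date(character()),
                         discharge_date = as.Date(character()),
                         icd_code = character(), dx_type = character())
  tab <- dplyr::bind_rows(c(list(base), ev$inp))
  dplyr::arrange(tab, .data$person_id, .data$admission_date, .data$icd_code)
}

collect_procedures <- function(ev) {
  base <- tibble::tibble(person_id = character(), date = as.Date(character()),
                         proc_class = character())
  tab <- dplyr::bind_rows(c(list(base), ev$proc))
  dplyr::arrange(tab, .data$person_id, .data$date, .data$proc_class)
}

sample_site_icd <- function(site_name, n) {
  if (n == 0) return(character(0))
  switch(site_name,
    BREAST = sprintf("C50.%d", sample(0:9, n, replace = TRUE)),
    PROSTATE = rep("C61", n),
    COLORECTAL = {
      pre <- sample(c("C18", "C19", "C20", "C21"), n, replace = TRUE,
                    prob = c(0.55, 0.05, 0.3, 0.1))
      suf <- sample(0:9, n, replace = TRUE)
      ifelse(pre == "C18", sprintf("%s.%d", pre, suf), pre)
    }
  )
}

# all coding events of one site: index + follow-up + status-post coding of
# episodes (incident onsets and recurrences), surveillance coding of
# prevalent disease, pre-onset miscoding, suspected-only and excluded noise
code_site_events <- function(ev, site_name, dm, x, person_id, sex,
                             obs_start_qi, obs_end_qi, config) {
  cd <- dm$coding
  site <- cancer_site(site_name)
  n <- length(person_id)
  elig <- sex %in% site$eligible_sexes

  episodes <- dplyr::bind_rows(
    tibble::tibble(row = which(is.finite(x$onset_qi)),
                   ep_qi = x$onset_qi[is.finite(x$onset_qi)],
                   recurrence = FALSE),
    tibble::tibble(row = which(is.finite(x$rec_qi)),
                   ep_qi = x$rec_qi[is.finite(x$rec_qi)],
                   recurrence = TRUE)
  )
  if (nrow(episodes)) {
    episodes <- episodes |>
      dplyr::mutate(
        obs_lo = obs_start_qi[.data$row],
        obs_hi = obs_end_qi[.data$row],
        watchful = stats::runif(dplyr::n()) < cd$watchful_fraction,
        p_fu = dplyr::if_else(.data$watchful, cd$watchful_p_followup,
                              cd$p_followup_g)
      )

    # index-quarter coding
    idx <- episodes |>
      dplyr::filter(stats::runif(dplyr::n()) < cd$p_index_coded,
                    .data$ep_qi >= .data$obs_lo, .data$ep_qi <= .data$obs_hi) |>
      dplyr::mutate(inpatient = stats::runif(dplyr::n()) < cd$p_index_inpatient)
    out_idx <- dplyr::filter(idx, !.data$inpatient)
    push(ev, "out", tibble::tibble(
      person_id = person_id[out_idx$row],
      quarter = format_quarter(out_idx$ep_qi),
      icd_code = sample_site_icd(site_name, nrow(out_idx)),
      certainty = "G"
    ))
    inp_idx <- dplyr::filter(idx, .data$inpatient)
    if (nrow(inp_idx)) {
      dis <- random_day_in_quarter(inp_idx$ep_qi)
      adm <- pmax(dis - sample(0:9, nrow(inp_idx), replace = TRUE),
                  lubridate::make_date(quarter_year(inp_idx$ep_qi),
                                       3L * (quarter_of_year(inp_idx$ep_qi) - 1L) + 1L,
                                       1L))
      push(ev, "inp", tibble::tibble(
        person_id = person_id[inp_idx$row], admission_date = adm,
        discharge_date = dis,
        icd_code = sample_site_icd(site_name, nrow(inp_idx)),
        dx_type = "MAIN_DISCHARGE"
      ))
    }

    # follow-up G coding
    fu <- episodes |>
      tidyr::expand_grid(k = seq_len(max(cd$followup_quarters, 0L))) |>
      dplyr::mutate(qi = .data$ep_qi + .data$k) |>
      dplyr::filter(stats::runif(dplyr::n()) < .data$p_fu,
                    .data$qi >= .data$obs_lo, .data$qi <= .data$obs_hi)
    push(ev, "out", tibble::tibble(
      person_id = person_id[fu$row], quarter = format_quarter(fu$qi),
      icd_code = sample_site_icd(site_name, nrow(fu)), certainty = "G"
    ))

    # occasional ancillary hospital diagnosis during follow-up
    anc <- episodes |>
      dplyr::filter(stats::runif(dplyr::n()) < cd$p_ancillary) |>
      dplyr::mutate(qi = .data$ep_qi +
                      sample.int(max(cd$followup_quarters, 1L),
                                 dplyr::n(), replace = TRUE)) |>
      dplyr::filter(.data$qi >= .data$obs_lo, .data$qi <= .data$obs_hi)
    if (nrow(anc)) {
      dis <- random_day_in_quarter(anc$qi)
      push(ev, "inp", tibble::tibble(
        person_id = person_id[anc$row],
        admission_date = dis - sample(0:5, nrow(anc), replace = TRUE),
        discharge_date = dis,
        icd_code = sample_site_icd(site_name, nrow(anc)),
        dx_type = "ANCILLARY"
      ))
    }

    # status-post coding after the acute phase
    if (cd$z_quarters > cd$followup_quarters && cd$p_z_post > 0) {
      zz <- episodes |>
        tidyr::expand_grid(k = seq(cd$followup_quarters + 1L, cd$z_quarters)) |>
        dplyr::mutate(qi = .data$ep_qi + .data$k) |>
        dplyr::filter(stats::runif(dplyr::n()) < cd$p_z_post,
                      .data$qi >= .data$obs_lo, .data$qi <= .data$obs_hi)
      push(ev, "out", tibble::tibble(
        person_id = person_id[zz$row], quarter = format_quarter(zz$qi),
        icd_code = sample_site_icd(site_name, nrow(zz)), certainty = "Z"
      ))
    }

    # surgical treatment close to the episode start
    if (cd$p_surgery > 0 && length(site$surgery_classes)) {
      p_surg <- dplyr::if_else(episodes$recurrence,
                               cd$p_surgery * cd$recurrence_surgery_factor,
                               cd$p_surgery)
      sg <- episodes |>
        dplyr::filter(stats::runif(dplyr::n()) < p_surg,
                      .data$ep_qi >= .data$obs_lo, .data$ep_qi <= .data$obs_hi)
      if (nrow(sg)) {
        date <- random_day_in_quarter(sg$ep_qi) +
          floor(stats::runif(nrow(sg)) * (cd$surgery_max_delay_days + 1L))
        ok <- date_to_quarter(date) <= sg$obs_hi
        push(ev, "proc", tibble::tibble(
          person_id = person_id[sg$row[ok]], date = date[ok],
          proc_class = sample(site$surgery_classes, sum(ok), replace = TRUE)
        ))
      }
    }

    # spurious certain-coded diagnosis before true onset (workup miscoding)
    mc <- episodes |>
      dplyr::filter(!.data$recurrence,
                    stats::runif(dplyr::n()) < cd$p_history_miscode,
                    .data$ep_qi > .data$obs_lo) |>
      dplyr::mutate(qi = .data$obs_lo +
                      floor(stats::runif(dplyr::n()) *
                              (.data$ep_qi - .data$obs_lo)))
    push(ev, "out", tibble::tibble(
      person_id = person_id[mc$row], quarter = format_quarter(mc$qi),
      icd_code = sample_site_icd(site_name, nrow(mc)), certainty = "G"
    ))
  }

  # surveillance coding of prevalent disease (until recurrence, if any)
  prev_rows <- which(x$prev)
  if (length(prev_rows) &&
      (cd$p_z_prevalent > 0 || cd$p_g_prevalent > 0)) {
    surv_hi <- pmin(obs_end_qi[prev_rows],
                    ifelse(is.finite(x$rec_qi[prev_rows]),
                           x$rec_qi[prev_rows] - 1, Inf))
    pv <- tibble::tibble(row = prev_rows, lo = obs_start_qi[prev_rows],
                         hi = surv_hi) |>
      dplyr::filter(.data$hi >= .data$lo) |>
      dplyr::mutate(nq = as.integer(.data$hi - .data$lo + 1L)) |>
      tidyr::uncount(.data$nq, .id = "k") |>
      dplyr::mutate(qi = .data$lo + .data$k - 1L,
                    u = stats::runif(dplyr::n()),
                    kind = dplyr::case_when(
                      .data$u < cd$p_z_prevalent ~ "Z",
                      .data$u < cd$p_z_prevalent + cd$p_g_prevalent ~ "G",
                      TRUE ~ NA_character_
                    )) |>
      dplyr::filter(!is.na(.data$kind))
    push(ev, "out", tibble::tibble(
      person_id = person_id[pv$row], quarter = format_quarter(pv$qi),
      icd_code = sample_site_icd(site_name, nrow(pv)), certainty = pv$kind
    ))
  }

  # suspected-only and excluded-diagnosis noise among the disease free
  disease_free <- elig & !x$prev & !is.finite(x$onset_qi)
  v_flag <- disease_free & stats::runif(n) < cd$p_suspected_only
  v_rows <- which(v_flag & obs_end_qi >= obs_start_qi)
  if (length(v_rows)) {
    qi <- obs_start_qi[v_rows] +
      floor(stats::runif(length(v_rows)) *
              (obs_end_qi[v_rows] - obs_start_qi[v_rows] + 1))
    push(ev, "out", tibble::tibble(
      person_id = person_id[v_rows], quarter = format_quarter(qi),
      icd_code = sample_site_icd(site_name, length(v_rows)), certainty = "V"
    ))
  }
  a_rows <- which(disease_free & !v_flag &
                    stats::runif(n) < cd$p_excluded_dx &
                    obs_end_qi >= obs_start_qi)
  if (length(a_rows)) {
    qi <- obs_start_qi[a_rows] +
      floor(stats::runif(length(a_rows)) *
              (obs_end_qi[a_rows] - obs_start_qi[a_rows] + 1))
    push(ev, "out", tibble::tibble(
      person_id = person_id[a_rows], quarter = format_quarter(qi),
      icd_code = sample_site_icd(site_name, length(a_rows)), certainty = "A"
    ))
  }
  ev$v_flag[[site_name]] <- v_flag
  invisible(ev)
}

# unrelated outpatient diagnoses so that cancer codes sit in realistic noise
code_benign_events <- function(ev, config, person_id, obs_start_qi,
                               obs_end_qi) {
  if (config$benign_dx_mean <= 0) return(invisible(ev))
  n <- length(person_id)
  k <- stats::rpois(n, config$benign_dx_mean)
  rows <- rep(seq_len(n), k)
  rows <- rows[obs_end_qi[rows] >= obs_start_qi[rows]]
  if (!length(rows)) return(invisible(ev))
  qi <- obs_start_qi[rows] +
    floor(stats::runif(length(rows)) *
            (obs_end_qi[rows] - obs_start_qi[rows] + 1))
  codes <- sample(c("I10.90", "E11.9", "M54.5", "J06.9", "K21.0", "E78.0"),
                  length(rows), replace = TRUE)
  push(ev, "out", tibble::tibble(
    person_id = person_id[rows], quarter = format_quarter(qi),
    icd_code = codes,
    certainty = sample(c("G", "V"), length(rows), replace = TRUE,
                       prob = c(0.9, 0.1))
  ))
  invisible(ev)
}

# one or two spells per person; an optional mid-coverage gap
build_spells <- function(person_id, start, end, enr, span_end) {
  n <- length(person_id)
  span_days <- as.integer(end - start)
  gap <- stats::runif(n) < enr$p_gap & span_days > 120
  gap_len <- 1L + safe_rgeom(n, 1 / enr$gap_mean_days)
  gap_len <- as.integer(pmin(gap_len, pmax(span_days - 90L, 1L)))
  gap_start <- start + 30L +
    floor(stats::runif(n) * pmax(span_days - 60L - gap_len, 1L))
  first_end <- dplyr::if_else(gap, gap_start - 1L, end)
  tabs <- list(
    tibble::tibble(person_id = person_id, start = start, end = first_end),
    tibble::tibble(person_id = person_id[gap],
                   start = (gap_start + gap_len)[gap], end = end[gap])
  )
  dplyr::bind_rows(tabs) |>
    dplyr::filter(.data$start <= .data$end) |>
    dplyr::arrange(.data$person_id, .data$start)
}

#' Registry-style benchmark from ground truth
#'
#' Computes the age-standardised cumulative incidence that an ideal,
#' complete cancer registry would report for the simulated population:
#' directly from ground-truth onsets in the study year, standardised with
#' the same standard population used for the claims-based estimates. The
#' registry population comprises all generated persons with known sex and
#' birth year and a German state of residence, regardless of insurance
#' continuity.
#'
#' For the single-sex sites the rows carry `sex = "ALL"` (the eligible sex
#' is implicit); colorectal additionally gets `F` and `M` rows. `state =
#' "ALL"` rows give the national rate.
#'
#' @param population A [generate_population()] result.
#' @param std Standard population (default [esp1976()]).
#' @return Benchmark tibble (`site`, `sex`, `state`, `aci`) suitable for
#'   [compare_benchmark()].
#' @export
generate_registry_benchmark <- function(population, std = esp1976()) {
  config <- attr(population, "config")
  study_year <- if (!is.null(config)) config$study_year else 2013L
  pop <- population$persons |>
    dplyr::filter(.data$sex %in% c("F", "M"), !is.na(.data$birth_year),
                  .data$state %in% german_states()) |>
    dplyr::mutate(age_band = age_band(study_year - .data$birth_year))
  truth <- population$ground_truth |>
    dplyr::filter(.data$case_type == "INCIDENT_2013") |>
    dplyr::inner_join(pop, by = "person_id")

  one <- function(site_name, sex_val, state_val) {
    site <- cancer_site(site_name)
    p <- dplyr::filter(pop, .data$sex %in% site$eligible_sexes)
    t <- dplyr::filter(truth, .data$site == site_name)
    if (sex_val != "ALL") {
      p <- dplyr::filter(p, .data$sex == sex_val)
      t <- dplyr::filter(t, .data$sex == sex_val)
    }
    if (state_val != "ALL") {
      p <- dplyr::filter(p, .data$state == state_val)
      t <- dplyr::filter(t, .data$state == state_val)
    }
    bands <- p |>
      dplyr::count(.data$age_band, name = "persons") |>
      dplyr::left_join(dplyr::count(t, .data$age_band, name = "cases"),
                       by = "age_band") |>
      dplyr::mutate(cases = dplyr::coalesce(.data$cases, 0L))
    aci <- if (nrow(p) > 0) {
      suppressWarnings(age_standardized_cumulative_incidence(bands, std))
    } else NA_real_
    tibble::tibble(site = site_name, sex = sex_val, state = state_val,
                   aci = aci)
  }

  combos <- dplyr::bind_rows(
    tidyr::expand_grid(site = c("BREAST", "PROSTATE"), sex = "ALL",
                       state = c("ALL", german_states())),
    tidyr::expand_grid(site = "COLORECTAL", sex = c("ALL", "F", "M"),
                       state = c("ALL", german_states()))
  )
  purrr::pmap(combos, one) |> purrr::list_rbind()
}

`%||%` <- function(x, y) if (is.null(x)) y else x
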