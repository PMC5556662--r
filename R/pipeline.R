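#' Pipeline run configuration
#'
#' Orchestrates simulate/read -> cohort -> identify -> incidence ->
#' benchmark as one reproducible run. Exactly one of `input_dir` (claims
#' tables on disk) or `simulation` (a [sim_config()], a list of
#' [sim_config()] arguments, or a path to a YAML config) must be given.
#'
#' @param out_dir Output directory for all stage files.
#' @param input_dir Directory with existing claims tables, or `NULL`.
#' @param simulation Simulation config (object, argument list or YAML
#'   path), or `NULL`.
#' @param cohort List of [cohort_spec()] arguments (`reference_date`,
#'   `required_years`, `max_gap_days`).
#' @param sites `"all"` or a vector of site names.
#' @param algorithms `"all"` or a vector of grid labels.
#' @param strata Stratifications for the results table.
#' @param benchmark `"ground_truth"` to derive a registry-style benchmark
#'   from the simulated truth, a path to a `benchmark.csv`, or `NULL` to
#'   skip benchmarking.
#' @param seed Optional integer overriding the simulation seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, input_dir = NULL, simulation = NULL,
                       cohort = list(), sites = "all", algorithms = "all",
                       strata = c("overall", "sex", "state"),
                       benchmark = "ground_truth", seed = NULL) {
  if (is.null(input_dir) == is.null(simulation)) {
    rlang::abort("exactly one of `input_dir` and `simulation` must be set",
                 class = "oncoclaims_config_error")
  }
  if (is.character(simulation) && length(simulation) == 1) {
    simulation <- read_sim_config(simulation)
  } else if (is.list(simulation) && !inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  if (!identical(algorithms, "all")) {
    bad <- setdiff(algorithms, names(algorithm_grid()))
    if (length(bad)) {
      rlang::abort(paste("unknown algorithm label(s):",
                         paste(bad, collapse = ", ")),
                   class = "oncoclaims_config_error")
    }
  }
  if (!identical(sites, "all")) {
    sites <- toupper(sites)
    bad <- setdiff(sites, cancer_sites())
    if (length(bad)) {
      rlang::abort(paste("unknown site(s):", paste(bad, collapse = ", ")),
                   class = "oncoclaims_config_error")
    }
    if (!identical(algorithms, "all")) {
      grid <- algorithm_grid()
      su <- algorithms[purrr::map_lgl(algorithms,
                                      ~ grid[[.x]]$require_surgery_confirm)]
      if (length(su) && "PROSTATE" %in% sites) {
        rlang::abort(
          sprintf("algorithm(s) %s require surgical confirmation, undefined for PROSTATE",
                  paste(su, collapse = ", ")),
          class = "oncoclaims_config_error"
        )
      }
    }
  }
  structure(
    list(out_dir = out_dir, input_dir = input_dir, simulation = simulation,
         cohort = utils::modifyList(
           list(reference_date = "2013-01-01", required_years = 7,
                max_gap_days = 28),
           cohort
         ),
         sites = sites, algorithms = algorithms, strata = strata,
         benchmark = benchmark, seed = seed),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with [run_config()] fields; a `simulation` block
#'   is interpreted as [sim_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage and writes its outputs under `config$out_dir`:
#' the (simulated) claims tables, `cohort.csv`, `exclusions.json`,
#' `cases.csv`, `results.csv`, `benchmark.csv` and
#' `benchmark_comparison.csv` (when benchmarking is enabled),
#' `validation.csv` (when ground truth is available) and a
#' `manifest.json` recording the configuration hash, seed, per-stage row
#' counts, per-algorithm numerators and a content hash of every output
#' file. Reruns with an identical configuration are bit-identical.
#' One structured log line per stage goes to standard error.
#'
#' @param config A [run_config()] (or a YAML path).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulation)) {
    claims <- generate_population(config$simulation, seed = config$seed)
    write_claims_tables(claims, file.path(out_dir, "data"))
    stage_log("simulate", "%d persons, %d outpatient dx, %d inpatient dx",
              nrow(claims$persons), nrow(claims$outpatient),
              nrow(claims$inpatient))
  } else {
    claims <- read_claims_tables(config$input_dir, quiet = TRUE)
    gt_path <- file.path(config$input_dir, "ground_truth.csv")
    if (file.exists(gt_path)) {
      claims$ground_truth <- readr::read_csv(
        gt_path, col_types = readr::cols(.default = readr::col_character()),
        progress = FALSE
      )
    }
    stage_log("read", "%d persons from %s", nrow(claims$persons),
              config$input_dir)
  }

  spec <- do.call(cohort_spec, config$cohort)
  cohort <- build_cohort(claims$persons, claims$spells, spec)
  excl <- attr(cohort, "exclusions")
  readr::write_csv(
    tibble::as_tibble(cohort) |>
      dplyr::mutate(death_date = format(.data$death_date, "%Y-%m-%d")) |>
      dplyr::select("person_id", "sex", "age", "state"),
    file.path(out_dir, "cohort.csv"), na = "", progress = FALSE
  )
  jsonlite::write_json(as.list(excl), file.path(out_dir, "exclusions.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_log("cohort", "%d eligible, %d excluded", nrow(cohort), sum(excl))

  study_year <- lubridate::year(spec$reference_date)
  cases <- identify_cases(claims, cohort, config$sites, config$algorithms,
                          study_year = study_year)
  readr::write_csv(tibble::as_tibble(cases), file.path(out_dir, "cases.csv"),
                   progress = FALSE)
  stage_log("identify", "%d cases across %d site x algorithm cells",
            nrow(cases),
            nrow(dplyr::distinct(cases, .data$site, .data$algorithm_label)))

  results <- stratified_results(cases, cohort, strata = config$strata)
  readr::write_csv(tibble::as_tibble(results),
                   file.path(out_dir, "results.csv"), progress = FALSE)
  stage_log("incidence", "%d result rows", nrow(results))

  comparison <- NULL
  if (!is.null(config$benchmark)) {
    benchmark <- if (identical(config$benchmark, "ground_truth")) {
      if (is.null(claims$ground_truth)) {
        rlang::abort("benchmark = 'ground_truth' needs a ground-truth table",
                     class = "oncoclaims_data_error")
      }
      generate_registry_benchmark(claims)
    } else {
      readr::read_csv(config$benchmark,
                      col_types = readr::cols(aci = "d", .default = "c"),
                      progress = FALSE)
    }
    readr::write_csv(benchmark, file.path(out_dir, "benchmark.csv"),
                     progress = FALSE)
    comparison <- compare_benchmark(results, benchmark)
    readr::write_csv(tibble::as_tibble(comparison),
                     file.path(out_dir, "benchmark_comparison.csv"),
                     progress = FALSE)
    stage_log("benchmark", "%d compared strata", nrow(comparison))
  }

  validation <- NULL
  if (!is.null(claims$ground_truth)) {
    cells <- dplyr::distinct(tibble::as_tibble(cases), .data$site,
                             .data$algorithm_label)
    validation <- purrr::pmap(cells, function(site, algorithm_label) {
      glance(validation_metrics(cases, claims$ground_truth, cohort, site,
                                algorithm_label))
    }) |>
      purrr::list_rbind()
    readr::write_csv(validation, file.path(out_dir, "validation.csv"),
                     progress = FALSE)
    stage_log("validate", "%d algorithm cells scored", nrow(validation))
  }

  manifest <- build_manifest(config, claims, cohort, cases, results, out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("manifest", "written to %s", file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

build_manifest <- function(config, claims, cohort, cases, results, out_dir) {
  numerators <- tibble::as_tibble(cases) |>
    dplyr::count(.data$site, .data$algorithm_label, name = "numerator")
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  hashes <- purrr::map_chr(files, function(f) {
    rlang::hash(readChar(file.path(out_dir, f),
                         file.size(file.path(out_dir, f)), useBytes = TRUE))
  })
  cfg_id <- unclass(config)
  cfg_id$out_dir <- NULL  # the hash identifies the analysis, not its location
  list(
    config_hash = rlang::hash(cfg_id),
    seed = config$seed %||%
      (if (!is.null(config$simulation)) config$simulation$seed else NULL),
    row_counts = list(
      persons = nrow(claims$persons), spells = nrow(claims$spells),
      outpatient = nrow(claims$outpatient),
      inpatient = nrow(claims$inpatient),
      procedures = nrow(claims$procedures),
      cohort = nrow(cohort), cases = nrow(cases), results = nrow(results)
    ),
    exclusions = as.list(attr(cohort, "exclusions")),
    numerators = numerators,
    files = stats::setNames(as.list(hashes), files)
  )
}

#' Denominator sensitivity analysis
#'
#' Recomputes the incidence results under the three denominator regimes:
#' the main cohort (default 7 years of continuous insurance), a minimum of
#' 1 year (`min1y`), and a per-lookback regime in which each algorithm's
#' cohort requires continuous insurance of at least its own lookback length
#' (so L1..L7 get different denominators). Cohorts and identification runs
#' are shared between regimes wherever the required length coincides.
#'
#' @param claims A `claims_tables` list.
#' @param sites,algorithms Selections as in [identify_cases()].
#' @param reference_date,max_gap_days Cohort parameters.
#' @param main_required_years Continuous-insurance requirement of the main
#'   regime.
#' @param strata Stratifications for the results.
#' @return A tibble of class `incidence_result` with a leading `regime`
#'   column (`main`, `min1y`, `per_lookback`).
#' @export
run_sensitivity_analysis <- function(claims, sites = "all",
                                     algorithms = "all",
                                     reference_date = "2013-01-01",
                                     max_gap_days = 28,
                                     main_required_years = 7,
                                     strata = "overall") {
  grid <- algorithm_grid()
  if (identical(algorithms, "all")) algorithms <- names(grid)
  lookbacks <- purrr::map_int(grid[algorithms], "lookback_years")
  needed_years <- sort(unique(c(main_required_years, 1L, lookbacks)))

  study_year <- lubridate::year(parse_iso_date(reference_date))
  runs <- purrr::map(needed_years, function(y) {
    spec <- cohort_spec(reference_date, y, max_gap_days)
    cohort <- build_cohort(claims$persons, claims$spells, spec)
    cases <- identify_cases(claims, cohort, sites, algorithms,
                            study_year = study_year)
    list(cohort = cohort, cases = cases)
  })
  names(runs) <- as.character(needed_years)

  results_for <- function(years, labels) {
    run <- runs[[as.character(years)]]
    cases <- dplyr::filter(tibble::as_tibble(run$cases),
                           .data$algorithm_label %in% labels)
    class(cases) <- c("incident_cases", class(cases))
    stratified_results(cases, run$cohort, strata = strata)
  }

  main <- results_for(main_required_years, algorithms) |>
    dplyr::mutate(regime = "main", .before = 1)
  min1 <- results_for(1L, algorithms) |>
    dplyr::mutate(regime = "min1y", .before = 1)
  perlb <- purrr::map(sort(unique(lookbacks)), function(L) {
    results_for(L, algorithms[lookbacks == L])
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(regime = "per_lookback", .before = 1)

  out <- dplyr::bind_rows(main, min1, perlb)
  class(out) <- c("incidence_result", class(out))
  out
}
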