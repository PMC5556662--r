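#' Cancer site definitions
#'
#' The three sites covered by the case-finding algorithms, defined by their
#' 3-character ICD-10-GM categories as used by the German Centre for Cancer
#' Registry Data: breast `C50` (women only), prostate `C61` (men only) and
#' colorectal `C18`-`C21` (women and men). Breast and colorectal sites carry
#' the abstract surgery classes admissible as confirmatory events
#' (lumpectomy/mastectomy; endoscopy/colorectal surgery); prostate has none.
#'
#' @param name One of `"BREAST"`, `"PROSTATE"`, `"COLORECTAL"`
#'   (case-insensitive).
#' @return A list of class `cancer_site` with elements `name`,
#'   `icd_prefixes`, `eligible_sexes` and `surgery_classes`.
#' @examples
#' cancer_site("breast")$icd_prefixes
#' @export
cancer_site <- function(name) {
  name <- toupper(name)
  defs <- list(
    BREAST = list(
      name = "BREAST",
      icd_prefixes = "C50",
      eligible_sexes = "F",
      surgery_classes = c("LUMPECTOMY", "MASTECTOMY")
    ),
    PROSTATE = list(
      name = "PROSTATE",
      icd_prefixes = "C61",
      eligible_sexes = "M",
      surgery_classes = character(0)
    ),
    COLORECTAL = list(
      name = "COLORECTAL",
      icd_prefixes = c("C18", "C19", "C20", "C21"),
      eligible_sexes = c("F", "M"),
      surgery_classes = c("ENDOSCOPY", "COLORECTAL_SURGERY")
    )
  )
  if (!name %in% names(defs)) {
    rlang::abort(
      sprintf("unknown cancer site '%s' (use BREAST, PROSTATE or COLORECTAL)",
              name),
      class = "oncoclaims_input_error"
    )
  }
  structure(defs[[name]], class = "cancer_site")
}

#' @rdname cancer_site
#' @export
cancer_sites <- function() c("BREAST", "PROSTATE", "COLORECTAL")

#' Match an ICD code against a site's diagnosis groups
#'
#' Matching is on the 3-character ICD-10 category only, case-insensitive and
#' dot-insensitive: `"C50.4"`, `"c504"` and `"C50"` all match the breast
#' group. Unknown or unrelated codes simply return `FALSE`.
#'
#' @param code Character vector of ICD-10-GM codes.
#' @param site A [cancer_site()] object or site name.
#' @return Logical vector.
#' @examples
#' icd_matches_site(c("C50.4", "C22.0"), "BREAST")
#' @export
icd_matches_site <- function(code, site) {
  site <- as_cancer_site(site)
  norm <- toupper(gsub(".", "", code, fixed = TRUE))
  substr(norm, 1, 3) %in% site$icd_prefixes
}

as_cancer_site <- function(site) {
  if (inherits(site, "cancer_site")) site else cancer_site(site)
}

#' @export
print.cancer_site <- function(x, ...) {
  cat(sprintf(
    "<cancer_site> %s: ICD %s; sexes %s; surgery classes: %s\n",
    x$name, paste(x$icd_prefixes, collapse = ","),
    paste(x$eligible_sexes, collapse = ","),
    if (length(x$surgery_classes)) paste(x$surgery_classes, collapse = ",")
    else "(none)"
  ))
  invisible(x)
}

# Closed sets used by table validation and the simulator.
certainty_levels <- function() c("G", "V", "Z", "A")
dx_type_levels <- function() c("MAIN_DISCHARGE", "ANCILLARY")
proc_class_levels <- function() {
  c("LUMPECTOMY", "MASTECTOMY", "ENDOSCOPY", "COLORECTAL_SURGERY", "OTHER")
}

#' German federal-state codes
#'
#' Two-letter codes for the 16 federal states (Laender), used for the
#' residence field and for state-stratified incidence. `FOREIGN` marks
#' residence outside Germany and `MISSING` an absent or invalid entry; both
#' are excluded from study cohorts.
#'
#' @return Character vector of the 16 state codes.
#' @export
german_states <- function() {
  c("BW", "BY", "BE", "BB", "HB", "HH", "HE", "MV",
    "NI", "NW", "RP", "SL", "SN", "ST", "SH", "TH")
}
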