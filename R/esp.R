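#' The 1976 European Standard Population
#'
#' Weight set used for direct age standardisation, in the 18-band form
#' (0-4, 5-9, ..., 80-84, 85+) conventional in German cancer-registry
#' reporting. Weights are per 100,000 and sum to exactly 100,000:
#' 8000 for 0-4, 7000 for each band from 5-9 through 55-59, then 6000,
#' 5000, 4000, 3000, 2000, 1000 and 1000 for 85+.
#'
#' @return A tibble with columns `age_band` (ordered factor), `age_lo`,
#'   `age_hi` (upper bound, `Inf` for 85+) and `weight`.
#' @examples
#' sum(esp1976()$weight)  # 100000
#' @export
esp1976 <- function() {
  lo <- seq(0L, 85L, by = 5L)
  hi <- c(seq(4L, 84L, by = 5L), Inf)
  w <- c(8000, rep(7000, 10), 6000, 5000, 4000, 3000, 2000, 1000, 1000)
  stopifnot(sum(w) == 100000)  # load-time guard on the standard
  tibble::tibble(
    age_band = factor(age_band_labels(), levels = age_band_labels(),
                      ordered = TRUE),
    age_lo = lo, age_hi = hi, weight = w
  )
}

age_band_labels <- function() {
  c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
}

#' Assign ages to 5-year standardisation bands
#'
#' @param age Integer ages in years (age in the study year, computed as
#'   study year minus birth year since claims carry only the birth year).
#' @return Ordered factor over the 18 bands `0-4` ... `85+`; `NA` ages map
#'   to `NA`.
#' @export
age_band <- function(age) {
  idx <- pmin(age %/% 5L, 17L) + 1L
  factor(age_band_labels()[idx], levels = age_band_labels(), ordered = TRUE)
}
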