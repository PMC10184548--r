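#' Scaled, log-transformed cochlear duct length
#'
#' The hearing proxy: endosseous cochlear duct (ECD) length scaled to
#' basicranial length (BCL) and log-transformed, `x = log10(ECD/BCL)`.
#' Base-10 logarithms are required for the published frequency equations to
#' reproduce their reference values. Negative whenever ECD < BCL, which is
#' always the case in practice.
#'
#' @param ecd_mm Endosseous cochlear duct length in mm (> 0, vectorised).
#' @param bcl_mm Basicranial length in mm (> 0, vectorised): anteroposterior
#'   distance from the anterior limit of the basisphenoid (excluding the
#'   cultriform process) to the posterior margin of the occipital condyle.
#' @return Dimensionless `x`.
#' @export
#' @examples
#' scaled_ecd(19.6, 104.5)
scaled_ecd <- function(ecd_mm, bcl_mm) {
  check_positive(ecd_mm, "ecd_mm")
  check_positive(bcl_mm, "bcl_mm")
  log10(ecd_mm / bcl_mm)
}

#' Best hearing range from the scaled cochlear proxy
#'
#' Linear calibration `y = 6104.3 x + 6975` Hz, `x` as in [scaled_ecd()].
#'
#' @param x Dimensionless scaled log cochlear length (finite, vectorised).
#' @return Best hearing range in Hz.
#' @export
best_hearing_range <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite.", call. = FALSE)
  }
  6104.3 * x + 6975
}

#' Mean best hearing frequency from the scaled cochlear proxy
#'
#' Linear calibration `y = 3311.3 x + 4000.8` Hz, `x` as in [scaled_ecd()].
#'
#' @inheritParams best_hearing_range
#' @return Mean best frequency in Hz.
#' @export
mean_best_frequency <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite.", call. = FALSE)
  }
  3311.3 * x + 4000.8
}

#' Hearing estimate from cochlear duct and basicranial lengths
#'
#' Composes [scaled_ecd()], [best_hearing_range()] and
#' [mean_best_frequency()]. Vectorised; pass the columns of a specimen table
#' directly. Frequencies are returned at full precision; the comparative
#' convention reports them to the nearest Hz (`rounding_profile()$hz`).
#'
#' @inheritParams scaled_ecd
#' @param taxon Optional label(s) carried through.
#' @return A tibble with columns `taxon` (if given), `ecd_mm`, `bcl_mm`, `x`,
#'   `best_range_hz`, `mean_freq_hz`.
#' @export
#' @examples
#' hearing_estimate(19.6, 104.5)  # ~2538 Hz best range, ~1594 Hz mean
hearing_estimate <- function(ecd_mm, bcl_mm, taxon = NULL) {
  x <- scaled_ecd(ecd_mm, bcl_mm)
  out <- tibble::tibble(
    ecd_mm = ecd_mm,
    bcl_mm = bcl_mm,
    x = x,
    best_range_hz = best_hearing_range(x),
    mean_freq_hz = mean_best_frequency(x)
  )
  if (!is.null(taxon)) out <- dplyr::bind_cols(tibble::tibble(taxon = taxon), out)
  out
}
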