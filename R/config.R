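#' Pipeline configuration
#'
#' Collects the tunable settings shared by the reporting surfaces: the
#' brain-fill fractions used for encephalisation, the rounding profile used
#' whenever a value is *presented* (stored values always keep full precision),
#' mesh strictness, and the default output format.
#'
#' @param fill_fractions Numeric vector of assumed brain:endocast volume
#'   fractions, each in (0, 1]. Defaults to the two conventions used for
#'   non-maniraptoriform dinosaurs, 37% and 50%.
#' @param strict_mesh If `TRUE` (default), volume computation refuses open
#'   meshes; if `FALSE`, the signed sum is computed anyway and flagged.
#' @param format Default output format for reports: `"json"`, `"csv"` or
#'   `"markdown"`.
#' @param rounding A rounding profile as produced by [rounding_profile()].
#'
#' @return A list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(fill_fractions = c(0.37, 0.5))
#' cfg$rounding$hz
pipeline_config <- function(fill_fractions = c(0.37, 0.50),
                            strict_mesh = TRUE,
                            format = c("json", "csv", "markdown"),
                            rounding = rounding_profile()) {
  if (!is.numeric(fill_fractions) || length(fill_fractions) < 1 ||
      any(!is.finite(fill_fractions)) ||
      any(fill_fractions <= 0 | fill_fractions > 1)) {
    stop("`fill_fractions` must be numeric values in (0, 1].", call. = FALSE)
  }
  structure(
    list(
      fill_fractions = fill_fractions,
      strict_mesh = isTRUE(strict_mesh),
      format = match.arg(format),
      rounding = rounding
    ),
    class = "pipeline_config"
  )
}

#' Rounding profile for reported quantities
#'
#' One place holding the decimal places used when quantities are reported, so
#' user output and the validation suite cannot drift apart. Frequencies are
#' reported to the nearest Hz, encephalisation quotients to 1 decimal place
#' (2 for fine comparisons), ratios to 2, percentages to 1, masses to the
#' nearest kilogram.
#'
#' @param hz,req,req_fine,ratio,percent,mass_kg Integer digit counts.
#' @return A named list of digit counts.
#' @export
rounding_profile <- function(hz = 0, req = 1, req_fine = 2, ratio = 2,
                             percent = 1, mass_kg = 0) {
  list(hz = hz, req = req, req_fine = req_fine, ratio = ratio,
       percent = percent, mass_kg = mass_kg)
}

#' Round half away from zero
#'
#' Presentation rounding used throughout the package. Unlike [round()], which
#' rounds half to even, ties go away from zero: the comparative literature
#' this package reproduces reports e.g. half of 150.5 as 75.3, not 75.2.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (may be negative).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(75.25, 1)   # 75.3
#' round(75.25, 1)           # 75.2 under half-to-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared input guard: positive, finite, numeric
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0.", name), call. = FALSE)
  }
  invisible(x)
}
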