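#' Bipedal body mass from minimum femoral circumference
#'
#' Developmental-mass allometry for bipeds:
#' \deqn{M_{Bd} = 10^{\,2.749\,\log_{10}(\sqrt{2}\,FC) - 1.104}\ \mathrm{g},}
#' where FC is the minimum femoral circumference in millimetres. The
#' \eqn{\sqrt{2}} factor converts the single femoral circumference to the
#' combined stylopodial circumference the quadrupedal scaling is built on.
#' The function is a pure power law in FC (exponent 2.749).
#'
#' @param fc_mm Minimum femoral circumference in mm (vectorised, > 0).
#' @return A tibble with columns `fc_mm`, `mass_g`, `mass_kg`.
#' @export
#' @examples
#' body_mass_bipedal(350)  # ~2011 kg
body_mass_bipedal <- function(fc_mm) {
  check_positive(fc_mm, "fc_mm")
  mass_g <- 10^(2.749 * log10(fc_mm * sqrt(2)) - 1.104)
  tibble::tibble(fc_mm = fc_mm, mass_g = mass_g, mass_kg = mass_g / 1000)
}

#' Brain mass from endocast volume and a fill fraction
#'
#' The brain of a non-maniraptoriform dinosaur did not fill its endocranial
#' cavity; brain mass is taken as a fixed fraction of endocast volume
#' (conventionally 37% or 50%) at a brain-tissue density of 1 g/cm^3, so
#' volume and mass are numerically interchangeable.
#'
#' @param ev_cm3 Endocast volume in cm^3 (> 0, vectorised).
#' @param fill_fraction Assumed brain:endocast volume fraction in (0, 1].
#' @return Brain mass in grams.
#' @export
#' @examples
#' brain_mass_from_endocast(150.5, 0.37)  # 55.685 g
brain_mass_from_endocast <- function(ev_cm3, fill_fraction) {
  check_positive(ev_cm3, "ev_cm3")
  if (!is.numeric(fill_fraction) || any(!is.finite(fill_fraction)) ||
      any(fill_fraction <= 0 | fill_fraction > 1)) {
    stop("`fill_fraction` must lie in (0, 1].", call. = FALSE)
  }
  ev_cm3 * fill_fraction * 1  # 1 g/cm^3
}

#' Reptile encephalisation quotient
#'
#' Observed brain mass over the mass predicted for a non-avian reptile of the
#' same body mass:
#' \deqn{REQ = \frac{M_{Br}}{0.0155\, M_{Bd}^{\,0.553}},}
#' with both masses in grams and brain mass excluding the olfactory tract and
#' bulbs. Strictly increasing in brain mass, strictly decreasing in body mass.
#'
#' @param brain_mass_g Brain mass in g (> 0, vectorised).
#' @param body_mass_g Body mass in g (> 0, vectorised).
#' @return Dimensionless REQ.
#' @export
#' @examples
#' req(75.2435, 2011000)  # ~1.59: an REQ above 1 means larger-brained
#'                        # than the average reptile of that body mass
req <- function(brain_mass_g, body_mass_g) {
  check_positive(brain_mass_g, "brain_mass_g")
  check_positive(body_mass_g, "body_mass_g")
  brain_mass_g / (0.0155 * body_mass_g^0.553)
}

#' Encephalisation table for one or more specimens
#'
#' Tidy wrapper composing [brain_mass_from_endocast()] and [req()] across the
#' configured fill fractions. Inputs recycle in the usual vectorised way; the
#' output has one row per specimen x fill fraction.
#'
#' @param ev_cm3 Endocast volume(s), cm^3.
#' @param body_mass_g Body mass(es), g.
#' @param fill_fractions Fractions in (0, 1]; default `c(0.37, 0.50)`.
#' @param taxon Optional label(s) carried through.
#' @return A tibble with columns `taxon` (if given), `ev_cm3`,
#'   `fill_fraction`, `brain_mass_g`, `body_mass_g`, `req`.
#' @export
#' @examples
#' encephalization(150.487, 2011000)
encephalization <- function(ev_cm3, body_mass_g,
                            fill_fractions = c(0.37, 0.50), taxon = NULL) {
  base <- tibble::tibble(ev_cm3 = ev_cm3, body_mass_g = body_mass_g)
  if (!is.null(taxon)) base$taxon <- taxon
  out <- tidyr::crossing(base, fill_fraction = fill_fractions) |>
    dplyr::mutate(
      brain_mass_g = brain_mass_from_endocast(.data$ev_cm3,
                                              .data$fill_fraction),
      req = req(.data$brain_mass_g, .data$body_mass_g)
    )
  front <- intersect(c("taxon", "ev_cm3", "fill_fraction"), names(out))
  dplyr::select(out, dplyr::all_of(front), dplyr::everything())
}
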