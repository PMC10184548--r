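#' Olfactory ratio
#'
#' Longest diameter of the olfactory bulb (any orientation) as a percentage of
#' the longest diameter of the cerebral hemisphere. Scale-invariant: only the
#' quotient matters. Raw ratios should not be compared across taxa of very
#' different body size; see [log_olfactory_point()].
#'
#' @param bulb_mm Olfactory bulb longest diameter, mm (> 0, vectorised).
#' @param cerebrum_mm Cerebral hemisphere longest diameter, mm (> 0).
#' @return Ratio in percent.
#' @export
#' @examples
#' olfactory_ratio(26.4, 52.2)  # ~50.6
olfactory_ratio <- function(bulb_mm, cerebrum_mm) {
  check_positive(bulb_mm, "bulb_mm")
  check_positive(cerebrum_mm, "cerebrum_mm")
  100 * bulb_mm / cerebrum_mm
}

#' Log-log coordinates for olfactory-ratio vs body-mass plots
#'
#' Returns `log10` of the percentage ratio and of body mass in grams — the
#' axes of the standard theropod olfactory-acuity regression plots, so points
#' computed here can be placed against a user-supplied reference regression
#' line (the published line's coefficients are not hard-coded; supply your
#' own slope/intercept on these axes).
#'
#' @param ratio_pct Olfactory ratio in percent (> 0, vectorised).
#' @param body_mass_g Body mass in g (> 0, vectorised).
#' @return A tibble with columns `log_ratio`, `log_body_mass`.
#' @export
#' @examples
#' log_olfactory_point(50.6, 2011000)
log_olfactory_point <- function(ratio_pct, body_mass_g) {
  check_positive(ratio_pct, "ratio_pct")
  check_positive(body_mass_g, "body_mass_g")
  tibble::tibble(log_ratio = log10(ratio_pct),
                 log_body_mass = log10(body_mass_g))
}

#' Olfactory-acuity scatter in log-log space
#'
#' Plots specimens by `log10(body mass, g)` against `log10(olfactory ratio,
#' %)`, optionally over a user-supplied reference regression line, with the
#' packaged comparative ratios (which lack published masses) shown as light
#' horizontal guides.
#'
#' @param data A data frame with columns `ratio_pct` and `body_mass_g`
#'   (optional `taxon` for labels).
#' @param reference_line Optional `c(intercept, slope)` on the log-log axes.
#' @param show_comparative Draw the packaged comparative ratios as horizontal
#'   guides? Default `TRUE`.
#' @return A ggplot object.
#' @export
#' @examples
#' pts <- data.frame(taxon = "Ceratosuchops", ratio_pct = 50.6,
#'                   body_mass_g = 2011000)
#' plot_olfactory_space(pts)
plot_olfactory_space <- function(data, reference_line = NULL,
                                 show_comparative = TRUE) {
  stopifnot(all(c("ratio_pct", "body_mass_g") %in% names(data)))
  pts <- dplyr::bind_cols(
    data,
    log_olfactory_point(data$ratio_pct, data$body_mass_g)
  )
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$log_body_mass,
                                         y = .data$log_ratio))
  if (isTRUE(show_comparative)) {
    ref <- load_reference_table("olfaction")
    guides <- log10(stats::na.omit((ref$ratio_pct_min + ref$ratio_pct_max) / 2))
    p <- p + ggplot2::geom_hline(yintercept = guides, colour = "grey85",
                                 linewidth = 0.3)
  }
  if (!is.null(reference_line)) {
    p <- p + ggplot2::geom_abline(intercept = reference_line[1],
                                  slope = reference_line[2],
                                  linetype = "dashed", colour = "grey40")
  }
  p <- p + ggplot2::geom_point(size = 2.5, colour = "#2c5f8a")
  if ("taxon" %in% names(pts)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$taxon),
                                vjust = -1, size = 3)
  }
  p + ggplot2::labs(x = "log10 body mass (g)",
                    y = "log10 olfactory ratio (%)") +
    ggplot2::theme_minimal()
}
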