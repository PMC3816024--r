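#' Plot methods
#'
#' `autoplot()` methods for the package's result tibbles: wall-factor energy
#' scans (factors versus incident energy), dose profiles (log-scale dose
#' versus distance), ratio tables (displacement ratios versus distance) and
#' fluence spectra.
#'
#' @param object a result object.
#' @param ... ignored.
#' @return A ggplot object.
#' @name irkwall-autoplot
NULL

#' @rdname irkwall-autoplot
#' @method autoplot irk_kwall_scan
#' @export
autoplot.irk_kwall_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "energy", "k_att", "k_sc", "k_wall"),
    cols = c("k_att", "k_sc", "k_wall"),
    names_to = "factor", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$energy, .data$value,
                                     colour = .data$factor)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "incident photon energy (MeV)", y = "correction factor",
                  colour = NULL)
}

#' @rdname irkwall-autoplot
#' @method autoplot irk_dose_profile
#' @export
autoplot.irk_dose_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$distance, .data$dose)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance from cavity axis (cm)",
                  y = "dose per history (Gy)",
                  title = paste("source:", object$source_position[1]))
}

#' @rdname irkwall-autoplot
#' @method autoplot irk_ratio_table
#' @export
autoplot.irk_ratio_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "distance", "ratio_A_over_central",
                  "ratio_B_over_central", "ratio_A_over_B"),
    cols = -"distance", names_to = "ratio", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$distance, .data$value,
                                     colour = .data$ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance from cavity axis (cm)", y = "dose ratio",
                  colour = NULL)
}

#' @rdname irkwall-autoplot
#' @method autoplot irk_spectrum
#' @export
autoplot.irk_spectrum <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes((.data$bin_lo + .data$bin_hi) / 2,
                               .data$fluence)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1]) +
    ggplot2::labs(x = "photon energy (MeV)", y = "relative fluence")
}
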