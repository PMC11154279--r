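# ggplot2 displays for the main result types

#' Plot a microbeam dose profile
#'
#' @param object A [reconstruct_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.microbeam_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position_um, y = .data$dose)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "lateral position (µm)", y = "dose",
                  title = sprintf("microbeam profile at y = %g mm",
                                  attr(object, "y_mm"))) +
    ggplot2::theme_minimal()
}

#' Plot a fluence pattern
#'
#' @param object A [fluence_pattern()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fluence_pattern <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position_um,
                               y = .data$relative_fluence)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "lateral position (µm)",
                  y = "relative primary fluence") +
    ggplot2::theme_minimal()
}

#' Plot peak/valley dose and PVDR against depth
#'
#' Peak and valley dose on a log scale against depth, with the annotated
#' valley maxima marked, plus a PVDR panel.
#'
#' @param object A [depth_dose_report()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_dose_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("depth_mm", "peak", "valley")],
    c("peak", "valley"), names_to = "component", values_to = "dose")
  mx <- attr(object, "valley_maxima")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$depth_mm, y = .data$dose,
                                          colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "depth (mm)", y = "dose (per history)") +
    ggplot2::theme_minimal()
  if (!is.null(mx) && nrow(mx)) {
    p <- p + ggplot2::geom_vline(xintercept = mx$depth_mm, linetype = 3)
  }
  p
}

#' Plot an X-ray spectrum
#'
#' @param object An [generate_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xray_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy_kev,
                                       y = .data$fluence)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "energy (keV)", y = "relative fluence") +
    ggplot2::theme_minimal()
}
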