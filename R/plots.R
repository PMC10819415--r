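#' Plot a signal-to-background depth profile
#'
#' Signal, background and their ratio against imaging depth on a log scale,
#' the standard way stack-analysis results are inspected.
#'
#' @param object An `sbr_profile` tibble from [sbr_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sbr_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "depth_um", "signal", "background", "ratio"),
    c("signal", "background", "ratio"),
    names_to = "quantity", values_to = "value"
  )
  long <- dplyr::filter(long, is.finite(.data$value), .data$value > 0)
  ggplot2::ggplot(long, ggplot2::aes(.data$depth_um, .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "imaging depth (µm)", y = "counts / ratio",
      colour = NULL, title = "Signal-to-background depth profile"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an SBR depth-scattering map
#'
#' Filled map of the simulated signal-to-background ratio over imaging
#' depth and scattering length, with iso-ratio contours at the standard
#' levels ([sbr_contour_levels()]).
#'
#' @param object An `sbr_map` tibble from [sbr_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sbr_map <- function(object, ...) {
  dat <- dplyr::filter(object, is.finite(.data$ratio), .data$ratio > 0)
  levels <- attr(object, "contour_levels")
  ggplot2::ggplot(dat, ggplot2::aes(.data$depth_um, .data$scattering_length_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(.data$ratio))) +
    ggplot2::geom_contour(ggplot2::aes(z = log10(.data$ratio)),
                          breaks = log10(levels), colour = "white",
                          linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "log10 SBR") +
    ggplot2::labs(
      x = "imaging depth (µm)", y = "scattering length (µm)",
      title = sprintf("Simulated %dP signal-to-background ratio",
                      object$order[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a power-series nonlinearity fit
#'
#' Log-log scatter of signal versus power with the fitted power law; the
#' slope is the excitation-order exponent.
#'
#' @param object A `power_fit` from [fit_power_exponent()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_fit <- function(object, ...) {
  ggplot2::ggplot(object$series, ggplot2::aes(.data$power, .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble::tibble(
        power = object$series$power,
        signal = exp(object$intercept) * object$series$power^object$exponent
      ),
      colour = "steelblue"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "excitation power (relative)", y = "signal (a.u.)",
      title = sprintf("S ~ P^%.2f", object$exponent)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an attenuation-length fit
#'
#' ln(power) versus depth with the fitted exponential power demand; the
#' inverse slope is the effective attenuation length.
#'
#' @param object An `attenuation_fit` from [estimate_attenuation_length()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attenuation_fit <- function(object, ...) {
  ggplot2::ggplot(object$schedule, ggplot2::aes(.data$depth_um, .data$power)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble::tibble(
        depth_um = object$schedule$depth_um,
        power = exp(stats::predict(object$fit))
      ),
      colour = "steelblue"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "imaging depth (µm)", y = "surface power (relative)",
      title = sprintf("attenuation length %.0f µm", object$le_um)
    ) +
    ggplot2::theme_minimal()
}
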