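#' Optical properties of the sample medium
#'
#' @param scattering_length_um Scattering length \eqn{l_e} in micrometres:
#'   the depth over which the unscattered (ballistic) fraction of the
#'   excitation light falls to 1/e. `Inf` for a non-scattering medium.
#' @param absorption_length_um Absorption length for the *emitted*
#'   fluorescence on its way back out of the sample, in micrometres.
#'   Default 500 (0.5 mm, appropriate for blue-green emission in a dense
#'   aqueous bacterial sample). `Inf` disables emission absorption.
#' @param fill_fraction Fraction of the sample volume occupied by
#'   fluorescent structures, in (0, 1]. Default 0.10 (a dense mycelium;
#'   labelled neurons in cortex would be nearer 0.01). The focal signal
#'   comes from a single structure while the background comes from the
#'   volume-averaged medium, so the signal-to-background ratio scales as
#'   `1 / fill_fraction`.
#'
#' @return An object of class `medium_properties`.
#' @export
#' @examples
#' medium_properties(scattering_length_um = 120)
medium_properties <- function(scattering_length_um,
                              absorption_length_um = 500,
                              fill_fraction = 0.10) {
  stopifnot(
    "scattering_length_um must be a single positive number" =
      is.numeric(scattering_length_um) && length(scattering_length_um) == 1 &&
        scattering_length_um > 0,
    "absorption_length_um must be a single positive number" =
      is.numeric(absorption_length_um) && length(absorption_length_um) == 1 &&
        absorption_length_um > 0,
    "fill_fraction must be in (0, 1]" =
      is.numeric(fill_fraction) && length(fill_fraction) == 1 &&
        fill_fraction > 0 && fill_fraction <= 1
  )
  structure(
    list(
      scattering_length_um = scattering_length_um,
      absorption_length_um = absorption_length_um,
      fill_fraction = fill_fraction
    ),
    class = "medium_properties"
  )
}

#' @export
print.medium_properties <- function(x, ...) {
  cat("<medium_properties>\n")
  cat(sprintf("  scattering length: %.4g um\n", x$scattering_length_um))
  cat(sprintf("  absorption length: %.4g um (emission)\n", x$absorption_length_um))
  cat(sprintf("  fill fraction:     %.4g\n", x$fill_fraction))
  invisible(x)
}

# Half-width of the focal integration window: excitation within +/- this
# axial distance of the geometric focus counts as signal, everything above
# it (up to the surface) as background.
FOCAL_HALFWIDTH_UM <- 5.8

# Axial integrand of the laterally integrated m-photon excitation, with the
# ballistic loss referenced to the sample surface at z = depth. Per z-slab,
# the lateral Gaussian integral is closed-form:
#   int I^m dx dy = (w0^2/w^2)^m * pi w^2 / (2 m)
#                 = pi w0^2/(2m) * (1 + (z/a)^2)^(1 - m),
# and the surface-referenced ballistic factor is exp(-m (depth - z) / le),
# folded in here (rather than as an outer prefactor) to avoid overflow at
# large depth / short scattering length.
axial_slab_integrand <- function(z_um, depth_um, beam, medium, m) {
  a <- beam$refractive_index * rayleigh_length(beam)
  le <- medium$scattering_length_um
  pref <- pi * beam$waist_um^2 / (2 * m)
  loss <- if (is.infinite(le)) 1 else exp(-m * (depth_um - z_um) / le)
  pref * (1 + (z_um / a)^2)^(1 - m) * loss
}

emission_factor <- function(path_um, medium) {
  if (is.infinite(medium$absorption_length_um)) {
    rep(1, length(path_um))
  } else {
    exp(-path_um / medium$absorption_length_um)
  }
}

#' Focal (in-focus) signal versus imaging depth
#'
#' Integrates the m-photon excitation density over the focal volume — the
#' full lateral plane within `focal_halfwidth_um` of the geometric focus —
#' for a focus placed `depth_um` below the sample surface. The surface power
#' is held fixed, so the ballistic scattering loss enters as
#' \eqn{e^{-m d / l_e}} overall; the result is boosted by
#' `1 / fill_fraction` (the focus sits on a fluorescent structure, not on
#' the volume-averaged medium) and attenuated by emission absorption
#' \eqn{e^{-d / L_a}}.
#'
#' @param depth_um Imaging depth(s) in micrometres (>= 0): distance from the
#'   sample surface to the focus.
#' @param beam A [beam_parameters()] object.
#' @param medium A [medium_properties()] object.
#' @param order Photon order m (2 or 3).
#' @param focal_halfwidth_um Half-width of the focal integration window in
#'   micrometres (default 5.8, about 3.5 in-medium Rayleigh lengths).
#' @return Focal signal in arbitrary units, vectorised over `depth_um`.
#' @export
focal_signal <- function(depth_um, beam, medium, order,
                         focal_halfwidth_um = FOCAL_HALFWIDTH_UM) {
  stopifnot(inherits(beam, "beam_parameters"), inherits(medium, "medium_properties"))
  m <- check_order(order)
  if (any(depth_um < 0)) stop("`depth_um` must be non-negative", call. = FALSE)
  vapply(depth_um, function(d) {
    core <- stats::integrate(
      axial_slab_integrand, -focal_halfwidth_um, focal_halfwidth_um,
      depth_um = d, beam = beam, medium = medium, m = m,
      rel.tol = 1e-9
    )$value
    core * emission_factor(d, medium) / medium$fill_fraction
  }, numeric(1))
}

#' Out-of-focus background signal versus imaging depth
#'
#' Integrates the m-photon excitation density generated *above* the focal
#' volume — from `focal_halfwidth_um` above the focus up to the sample
#' surface at `z = depth_um` — over the full lateral plane. Each slab's
#' fluorescence is attenuated by emission absorption over its own escape
#' path \eqn{e^{-(d - z)/L_a}}. No fill-fraction boost is applied: the
#' background comes from the volume-averaged medium. Depths inside the focal
#' window return 0.
#'
#' @inheritParams focal_signal
#' @return Background signal in the same arbitrary units as
#'   [focal_signal()], vectorised over `depth_um`.
#' @export
background_signal <- function(depth_um, beam, medium, order,
                              focal_halfwidth_um = FOCAL_HALFWIDTH_UM) {
  stopifnot(inherits(beam, "beam_parameters"), inherits(medium, "medium_properties"))
  m <- check_order(order)
  if (any(depth_um <= 0)) stop("`depth_um` must be positive", call. = FALSE)
  vapply(depth_um, function(d) {
    if (d <= focal_halfwidth_um) return(0)
    stats::integrate(
      function(z) {
        axial_slab_integrand(z, d, beam, medium, m) * emission_factor(d - z, medium)
      },
      focal_halfwidth_um, d,
      rel.tol = 1e-9
    )$value
  }, numeric(1))
}

#' Signal-to-background ratio versus imaging depth
#'
#' The ratio of [focal_signal()] to [background_signal()]. Depths inside
#' the focal window, where no background is generated, return `Inf`.
#'
#' @inheritParams focal_signal
#' @return A tibble with columns `depth_um`, `order`, `signal`,
#'   `background` and `ratio`, one row per depth.
#' @export
#' @examples
#' beam <- beam_parameters()
#' med <- medium_properties(scattering_length_um = 120, fill_fraction = 1)
#' sbr(c(100, 400, 800), beam, med, order = 3)
sbr <- function(depth_um, beam, medium, order,
                focal_halfwidth_um = FOCAL_HALFWIDTH_UM) {
  sig <- focal_signal(depth_um, beam, medium, order, focal_halfwidth_um)
  bg <- background_signal(pmax(depth_um, .Machine$double.eps), beam, medium,
                          order, focal_halfwidth_um)
  tibble::tibble(
    depth_um = depth_um,
    order = check_order(order),
    signal = sig,
    background = bg,
    ratio = ifelse(bg > 0, sig / bg, Inf)
  )
}

#' Imaging depth at which the SBR reaches a target ratio
#'
#' Solves `sbr(depth) == target_ratio` by bisection to 1 um tolerance. The
#' signal-to-background ratio is checked to be monotone decreasing over the
#' search bracket; if the target is never crossed an error is raised.
#'
#' @param target_ratio Target signal-to-background ratio (> 0); 1 marks the
#'   conventional depth limit where background equals signal.
#' @inheritParams focal_signal
#' @param bracket Two-element depth search bracket in micrometres.
#' @return Depth in micrometres.
#' @export
#' @examples
#' beam <- beam_parameters()
#' med <- medium_properties(scattering_length_um = 120, fill_fraction = 1)
#' depth_at_sbr(1, beam, med, order = 3)
depth_at_sbr <- function(target_ratio, beam, medium, order,
                         bracket = c(12, 2000),
                         focal_halfwidth_um = FOCAL_HALFWIDTH_UM) {
  stopifnot(
    "`target_ratio` must be a single positive number" =
      is.numeric(target_ratio) && length(target_ratio) == 1 && target_ratio > 0,
    "`bracket` must be an increasing pair of depths" =
      length(bracket) == 2 && bracket[1] < bracket[2]
  )
  lo <- max(bracket[1], focal_halfwidth_um + 1)
  hi <- bracket[2]
  ratio_at <- function(d) {
    sbr(d, beam, medium, order, focal_halfwidth_um)$ratio
  }
  probe <- ratio_at(seq(lo, hi, length.out = 25))
  if (any(diff(probe) > 1e-8 * pmax(probe[-length(probe)], 1))) {
    stop("signal-to-background ratio is not monotone decreasing over the bracket",
         call. = FALSE)
  }
  f <- function(d) ratio_at(d) - target_ratio
  flo <- probe[1] - target_ratio
  fhi <- probe[length(probe)] - target_ratio
  if (flo * fhi > 0) {
    stop(sprintf(
      "SBR does not cross %.3g within [%.0f, %.0f] um (ratio spans %.3g to %.3g)",
      target_ratio, lo, hi, probe[1], probe[length(probe)]
    ), call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 0.5)$root
}

#' Contour levels used for SBR depth-scattering maps
#'
#' The standard iso-ratio levels drawn on simulated maps, from comfortable
#' imaging (20:1) down to practically impossible (1:100).
#' @return Numeric vector of ratio levels.
#' @export
sbr_contour_levels <- function() {
  c(20, 10, 5, 2, 1, 1 / 2, 1 / 5, 1 / 10, 1 / 20, 1 / 50, 1 / 100)
}

#' Signal-to-background ratio map over depth and scattering length
#'
#' Evaluates the SBR model on a (scattering length, depth) grid for one
#' excitation order, producing the data behind depth-limit contour maps.
#'
#' @param depth_um Strictly increasing vector of imaging depths (um).
#' @param scattering_length_um Strictly increasing vector of scattering
#'   lengths (um).
#' @inheritParams focal_signal
#' @param medium_template A [medium_properties()] object supplying the
#'   absorption length and fill fraction; its scattering length is replaced
#'   by each grid value in turn.
#' @return A tibble of class `sbr_map` with columns `scattering_length_um`,
#'   `depth_um`, `order`, `signal`, `background`, `ratio`.
#' @seealso [autoplot.sbr_map()], [sbr_contour_levels()]
#' @export
sbr_map <- function(depth_um, scattering_length_um, beam, medium_template, order,
                    focal_halfwidth_um = FOCAL_HALFWIDTH_UM) {
  stopifnot(
    "`depth_um` must be strictly increasing" = all(diff(depth_um) > 0),
    "`scattering_length_um` must be strictly increasing" =
      all(diff(scattering_length_um) > 0),
    inherits(medium_template, "medium_properties")
  )
  rows <- purrr::map_dfr(scattering_length_um, function(le) {
    med <- medium_properties(
      scattering_length_um = le,
      absorption_length_um = medium_template$absorption_length_um,
      fill_fraction = medium_template$fill_fraction
    )
    dplyr::mutate(
      sbr(depth_um, beam, med, order, focal_halfwidth_um),
      scattering_length_um = le,
      .before = 1
    )
  })
  class(rows) <- c("sbr_map", class(rows))
  attr(rows, "contour_levels") <- sbr_contour_levels()
  rows
}
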