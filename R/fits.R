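#' Fit the excitation nonlinearity exponent of a power series
#'
#' The fluorescence generated by an m-photon process scales as the m-th
#' power of the excitation power, so the slope of log(signal) versus
#' log(power) identifies the (dominant) excitation order of a detection
#' channel: ~2 for pure two-photon, ~3 for pure three-photon, intermediate
#' for mixed channels.
#'
#' @param series A data frame with columns `power` (strictly increasing,
#'   positive) and `signal` (positive mean fluorescence per power level);
#'   e.g. the output of [generate_power_series()] for one channel.
#' @return An object of class `power_fit` with the fitted `exponent`
#'   (log-log slope), `intercept`, standard errors and residual RMS; the
#'   underlying [stats::lm] fit is kept in `$fit`. Supports [tidy()] and
#'   [glance()].
#' @export
#' @examples
#' s <- tibble::tibble(power = 1:5, signal = 2 * (1:5)^3)
#' fit_power_exponent(s)
fit_power_exponent <- function(series) {
  stopifnot(
    "`series` needs `power` and `signal` columns" =
      is.data.frame(series) && all(c("power", "signal") %in% names(series)),
    "at least 3 points are required" = nrow(series) >= 3
  )
  if (any(series$power <= 0) || any(series$signal <= 0)) {
    stop("powers and signals must be positive", call. = FALSE)
  }
  if (any(diff(series$power) <= 0)) {
    stop("powers must be strictly increasing", call. = FALSE)
  }
  fit <- stats::lm(log(signal) ~ log(power), data = series)
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(
      exponent = unname(cf["log(power)", "Estimate"]),
      exponent_se = unname(cf["log(power)", "Std. Error"]),
      intercept = unname(cf["(Intercept)", "Estimate"]),
      residual_rms = sqrt(mean(stats::residuals(fit)^2)),
      n = nrow(series),
      fit = fit,
      series = tibble::as_tibble(series)
    ),
    class = "power_fit"
  )
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf(
    "<power_fit> S ~ P^%.3f (se %.3f, n = %d, residual RMS %.3g in log space)\n",
    x$exponent, x$exponent_se, x$n, x$residual_rms
  ))
  invisible(x)
}

#' @rdname fit_power_exponent
#' @param x A `power_fit` object.
#' @param ... Unused.
#' @export
tidy.power_fit <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "exponent"),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p.value = unname(cf[, "Pr(>|t|)"])
  )
}

#' @rdname fit_power_exponent
#' @export
glance.power_fit <- function(x, ...) {
  tibble::tibble(
    exponent = x$exponent,
    std.error = x$exponent_se,
    residual_rms = x$residual_rms,
    r.squared = suppressWarnings(summary(x$fit))$r.squared,
    nobs = x$n
  )
}

#' Estimate the effective attenuation length from a power schedule
#'
#' When the surface power is adjusted at each depth to keep the focal
#' brightness constant, the required power follows
#' \eqn{P(d) = P_0 e^{d / l_e}}, so the slope of ln(power) versus depth is
#' \eqn{1 / l_e}. The estimate is invariant to the power units. A flat
#' schedule (slope ~ 0) returns an infinite attenuation length.
#'
#' @param schedule A data frame with columns `depth_um` (increasing) and
#'   `power` (positive), e.g. from [generate_power_schedule()]. Jittered,
#'   non-monotone depth schedules are accepted with a warning.
#' @return An object of class `attenuation_fit` with `le_um`, its standard
#'   error `le_se_um` (delta method), the log-linear `slope` and the
#'   underlying [stats::lm] fit. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' sched <- tibble::tibble(depth_um = seq(0, 500, 100),
#'                         power = exp(seq(0, 500, 100) / 170))
#' estimate_attenuation_length(sched)
estimate_attenuation_length <- function(schedule) {
  stopifnot(
    "`schedule` needs `depth_um` and `power` columns" =
      is.data.frame(schedule) && all(c("depth_um", "power") %in% names(schedule)),
    "at least 3 (depth, power) pairs are required" = nrow(schedule) >= 3
  )
  if (any(schedule$power <= 0)) stop("powers must be positive", call. = FALSE)
  if (any(diff(schedule$depth_um) <= 0)) {
    warning("depths are not strictly increasing; fitting anyway", call. = FALSE)
  }
  fit <- stats::lm(log(power) ~ depth_um, data = schedule)
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(cf["depth_um", "Estimate"])
  slope_se <- unname(cf["depth_um", "Std. Error"])
  if (abs(slope) < 1e-12) {
    le <- Inf
    le_se <- Inf
  } else {
    le <- 1 / slope
    le_se <- slope_se / slope^2
  }
  structure(
    list(
      le_um = le,
      le_se_um = le_se,
      slope = slope,
      slope_se = slope_se,
      n = nrow(schedule),
      fit = fit,
      schedule = tibble::as_tibble(schedule)
    ),
    class = "attenuation_fit"
  )
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf(
    "<attenuation_fit> le = %.4g um (se %.3g, n = %d)\n",
    x$le_um, x$le_se_um, x$n
  ))
  invisible(x)
}

#' @rdname estimate_attenuation_length
#' @param x An `attenuation_fit` object.
#' @param ... Unused.
#' @export
tidy.attenuation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "attenuation_length_um"),
    estimate = c(x$slope, x$le_um),
    std.error = c(x$slope_se, x$le_se_um)
  )
}

#' @rdname estimate_attenuation_length
#' @export
glance.attenuation_fit <- function(x, ...) {
  tibble::tibble(
    le_um = x$le_um,
    std.error = x$le_se_um,
    r.squared = suppressWarnings(summary(x$fit))$r.squared,
    nobs = x$n
  )
}

# Fit A * exp(-2 (t - t0)^2 / w^2) + B to a 1D profile and return the
# 1/e^2 radius w. Linear-scale fit with a constant-background nuisance term.
fit_gaussian_radius <- function(t, y) {
  b0 <- min(y)
  a0 <- max(y) - b0
  t0 <- t[which.max(y)]
  above <- y - b0 > a0 * exp(-2)
  w0 <- max(diff(range(t[above])) / 2, diff(range(t)) / 20)
  fml <- y ~ A * exp(-2 * (t - t0)^2 / w^2) + B
  start <- list(A = a0, t0 = t0, w = w0, B = b0)
  fit <- tryCatch(
    stats::nls(fml, data = data.frame(t = t, y = y), start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit) && requireNamespace("minpack.lm", quietly = TRUE)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = data.frame(t = t, y = y), start = start),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) stop("Gaussian profile fit failed", call. = FALSE)
  abs(unname(stats::coef(fit)["w"]))
}

#' Fit PSF radii from a bead stack
#'
#' Locates the brightest bead-like spot in a z-stack, extracts the x, y and
#' z intensity profiles through its centre and fits each with a Gaussian
#' (plus constant background) on the linear scale, reporting per-axis
#' 1/e\eqn{^2} radii. For a sub-resolution bead these approximate the
#' m-photon excitation PSF radii; for a finite bead they approximate the
#' bead-convolved PSF (see [psf_with_bead()]).
#'
#' @param stack An [image_stack()] containing at least one isolated bright
#'   spot.
#' @return A tibble with columns `axis` (`"x"`, `"y"`, `"z"`) and
#'   `radius_um`.
#' @export
fit_psf_radii <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  bg <- background_level(v)
  noise <- stats::mad(v, center = bg)
  if (max(v) <= bg + 8 * max(noise, 1)) {
    stop("no bead-like spot found: stack maximum is within the noise floor",
         call. = FALSE)
  }
  # 3-point boxcar along each axis knocks down hot pixels before locating
  # the peak
  sm <- v
  d <- dim(v)
  if (all(d >= 3)) {
    sm <- (v[c(1, 1:(d[1] - 1)), , ] + v + v[c(2:d[1], d[1]), , ]) / 3
    sm <- (sm[, c(1, 1:(d[2] - 1)), ] + sm + sm[, c(2:d[2], d[2]), ]) / 3
    sm <- (sm[, , c(1, 1:(d[3] - 1))] + sm + sm[, , c(2:d[3], d[3])]) / 3
  }
  idx <- arrayInd(which.max(sm), d)
  zi <- idx[1]; yi <- idx[2]; xi <- idx[3]

  prof_x <- v[zi, yi, ]
  prof_y <- v[zi, , xi]
  prof_z <- v[, yi, xi]

  tibble::tibble(
    axis = c("x", "y", "z"),
    radius_um = c(
      fit_gaussian_radius(seq_along(prof_x) * stack$pixel_size_um, prof_x),
      fit_gaussian_radius(seq_along(prof_y) * stack$pixel_size_um, prof_y),
      fit_gaussian_radius(seq_along(prof_z) * stack$z_step_um, prof_z)
    )
  )
}
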