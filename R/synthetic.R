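# Default relative power grid used by the power-series generator: 10 levels,
# log-spaced over a decade, normalised to the highest power.
#' Default excitation-power grid
#'
#' Ten relative power levels, logarithmically spaced over one decade and
#' normalised to the highest power, as used for nonlinearity
#' characterisation.
#' @return Numeric vector of length 10.
#' @export
default_power_grid <- function() {
  exp(seq(log(0.1), log(1), length.out = 10))
}

# Weight of the two-photon pathway in the mixed green channel. Calibrated
# once so that the net log-log slope of w2 P^2 + (1 - w2) P^3 over
# default_power_grid() equals 2.81, the intermediate nonlinearity of a
# detection window fed by both processes.
GREEN_WEIGHT_2P <- 0.0631117835

#' Mixing weights of the green (mixed-order) channel
#'
#' The green detection window receives both two- and three-photon excited
#' fluorescence. Its synthetic signal is `w2 * P^2 + (1 - w2) * P^3`, with
#' `w2` calibrated (a fixed, documented constant) so that the net log-log
#' slope over [default_power_grid()] is 2.81.
#' @return Named numeric vector with elements `m2` and `m3`.
#' @export
green_channel_weights <- function() {
  c(m2 = GREEN_WEIGHT_2P, m3 = 1 - GREEN_WEIGHT_2P)
}

# Lognormal multiplicative noise with unit mean and coefficient of
# variation cv.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

CHANNEL_ORDER <- c(blue = 3, green = NA, red = 2) # green is mixed

#' Generate synthetic fluorescence-versus-power series
#'
#' Emulates a nonlinearity-characterisation experiment: the mean
#' fluorescence in each detection channel at a series of excitation powers,
#' with multiplicative lognormal measurement noise. Channel defaults mirror
#' measured autofluorescence nonlinearities: blue (three-photon) exponent
#' 3.09, red (two-photon) exponent 1.96, and a green channel built as a
#' calibrated mixture of an m = 2 and an m = 3 pathway whose net log-log
#' slope is 2.81 (see [green_channel_weights()]).
#'
#' @param channels Which channels to generate.
#' @param powers Positive, strictly increasing excitation powers (relative
#'   units); default [default_power_grid()].
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (default 0.05).
#' @param exponents Named vector of pure power-law exponents for the blue
#'   and red channels.
#' @param seed Integer seed; fixed seed gives identical series. Each
#'   channel draws from its own derived seed, so a channel's series does
#'   not depend on which other channels are requested.
#' @return A tibble with columns `channel`, `power`, `signal`.
#' @export
#' @examples
#' generate_power_series(seed = 7) |> head()
generate_power_series <- function(channels = c("blue", "green", "red"),
                                  powers = default_power_grid(),
                                  noise_cv = 0.05,
                                  exponents = c(blue = 3.09, red = 1.96),
                                  seed = 7) {
  stopifnot(
    "`powers` must be positive and strictly increasing" =
      all(powers > 0) && all(diff(powers) > 0),
    "`noise_cv` must be >= 0" = is.numeric(noise_cv) && noise_cv >= 0
  )
  channels <- match.arg(channels, c("blue", "green", "red"), several.ok = TRUE)
  w <- green_channel_weights()
  purrr::map_dfr(channels, function(ch) {
    mean_signal <- switch(ch,
      blue = powers^exponents[["blue"]],
      red = powers^exponents[["red"]],
      green = w[["m2"]] * powers^2 + w[["m3"]] * powers^3
    )
    noise <- withr::with_seed(
      seed + match(ch, names(CHANNEL_ORDER)),
      lognormal_noise(length(powers), noise_cv)
    )
    tibble::tibble(channel = ch, power = powers, signal = mean_signal * noise)
  })
}

#' Generate a surface-power schedule for constant focal brightness
#'
#' Emulates the acquisition schedule used to estimate a sample's effective
#' attenuation length: the surface power needed to keep the focal
#' brightness constant grows as \eqn{e^{d / l_e}}, here with multiplicative
#' lognormal noise and an optional hard cap emulating the maximum available
#' laser power.
#'
#' @param le_um True attenuation length in micrometres (default 170, a
#'   low-density mycelium sample).
#' @param depths_um Imaging depths in micrometres.
#' @param base_power Power at zero depth (relative units).
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param max_power Hard cap on the deliverable power; capped entries are
#'   flagged in the `truncated` column.
#' @param seed Integer seed.
#' @return A tibble with columns `depth_um`, `power`, `truncated`.
#' @export
#' @examples
#' generate_power_schedule(seed = 3)
generate_power_schedule <- function(le_um = 170,
                                    depths_um = seq(0, 500, length.out = 6),
                                    base_power = 1,
                                    noise_cv = 0.05,
                                    max_power = Inf,
                                    seed = 3) {
  stopifnot(
    "`le_um` must be positive" = is.numeric(le_um) && le_um > 0,
    "`base_power` must be positive" = base_power > 0
  )
  ideal <- base_power * exp(depths_um / le_um)
  noisy <- ideal * withr::with_seed(seed, lognormal_noise(length(depths_um), noise_cv))
  truncated <- noisy > max_power
  tibble::tibble(
    depth_um = depths_um,
    power = pmin(noisy, max_power),
    truncated = truncated
  )
}

#' Generate a random filament scene
#'
#' Grows smooth 3D random-walk filaments (correlated step directions,
#' reflecting boundaries) and rasterises them as tubes of the given radius
#' into a voxel occupancy volume, until the occupied fraction reaches the
#' target fill. The morphology emulates a mycelium: an intertwined network
#' of micrometre-scale filaments occupying roughly 10% of the volume.
#'
#' @param volume_um Scene extent `c(x, y, z)` in micrometres.
#' @param voxel_um Isotropic voxel size in micrometres.
#' @param fill_fraction Target occupied volume fraction (realised fill lands
#'   within about 20% of this).
#' @param filament_radius_um Filament radius in micrometres (default 0.5).
#' @param step_um Random-walk step length.
#' @param persistence Direction correlation between consecutive steps, in
#'   [0, 1); higher is straighter.
#' @param seed Integer seed; scenes are fully deterministic given the seed.
#' @return An object of class `filament_scene`: voxel `density` array
#'   `[z, y, x]` in [0, 1], the polyline `filaments`, grid metadata and the
#'   realised fill fraction.
#' @export
#' @examples
#' sc <- generate_filament_scene(volume_um = c(15, 15, 15), seed = 1)
#' sc$realized_fill
generate_filament_scene <- function(volume_um = c(40, 40, 40),
                                    voxel_um = 0.5,
                                    fill_fraction = 0.10,
                                    filament_radius_um = 0.5,
                                    step_um = 1.0,
                                    persistence = 0.85,
                                    seed = 1) {
  stopifnot(
    "`volume_um` must have 3 positive extents" =
      length(volume_um) == 3 && all(volume_um > 0),
    "`fill_fraction` must be in (0, 1]" =
      fill_fraction > 0 && fill_fraction <= 1
  )
  if (any(volume_um < 4 * filament_radius_um)) {
    stop("volume must be at least 4 filament radii per side", call. = FALSE)
  }
  nx <- max(1L, round(volume_um[1] / voxel_um))
  ny <- max(1L, round(volume_um[2] / voxel_um))
  nz <- max(1L, round(volume_um[3] / voxel_um))

  # sphere stamp: voxel offsets within the filament radius
  rv <- ceiling(filament_radius_um / voxel_um)
  off <- as.matrix(expand.grid(dz = -rv:rv, dy = -rv:rv, dx = -rv:rv))
  off <- off[rowSums(off^2) * voxel_um^2 <= filament_radius_um^2 + 1e-9, ,
             drop = FALSE]
  n_off <- nrow(off)

  occ <- array(0, dim = c(nz, ny, nx))
  filaments <- list()
  n_vox <- as.double(nz) * ny * nx
  n_filled <- 0

  withr::with_seed(seed, {
    while (n_filled / n_vox < fill_fraction) {
      pos <- stats::runif(3) * volume_um
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      n_steps <- round(stats::runif(1, 20, 60) / step_um)
      path <- matrix(NA_real_, n_steps + 1, 3)
      path[1, ] <- pos
      for (s in seq_len(n_steps)) {
        dir <- persistence * dir + (1 - persistence) * stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        pos <- pos + step_um * dir
        # reflect at the boundaries
        for (k in 1:3) {
          if (pos[k] < 0) {
            pos[k] <- -pos[k]
            dir[k] <- -dir[k]
          }
          if (pos[k] > volume_um[k]) {
            pos[k] <- 2 * volume_um[k] - pos[k]
            dir[k] <- -dir[k]
          }
        }
        path[s + 1, ] <- pos
      }
      # rasterise the polyline: sample at sub-voxel spacing, stamp all
      # spheres in one vectorised pass
      n_sub <- max(2L, ceiling(2 * step_um / voxel_um))
      fr <- seq(0, 1, length.out = n_sub + 1)[-(n_sub + 1)]
      pts <- do.call(rbind, lapply(seq_len(n_steps), function(s) {
        outer(fr, path[s + 1, ] - path[s, ]) +
          matrix(path[s, ], length(fr), 3, byrow = TRUE)
      }))
      centres <- round(sweep(pts, 2, voxel_um, "/") + 0.5)
      ix <- rep(centres[, 1], each = n_off) + off[, "dx"]
      iy <- rep(centres[, 2], each = n_off) + off[, "dy"]
      iz <- rep(centres[, 3], each = n_off) + off[, "dz"]
      keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny & iz >= 1 & iz <= nz
      lin <- unique((ix[keep] - 1) * (nz * ny) + (iy[keep] - 1) * nz + iz[keep])
      n_filled <- n_filled + sum(occ[lin] == 0)
      occ[lin] <- 1
      filaments[[length(filaments) + 1]] <- path
    }
  })

  structure(
    list(
      density = occ,
      filaments = filaments,
      volume_um = volume_um,
      voxel_um = voxel_um,
      fill_fraction_target = fill_fraction,
      filament_radius_um = filament_radius_um,
      realized_fill = mean(occ > 0),
      seed = seed
    ),
    class = "filament_scene"
  )
}

#' @export
print.filament_scene <- function(x, ...) {
  cat(sprintf(
    "<filament_scene> %g x %g x %g um, %d filaments, fill %.3f (target %.3f)\n",
    x$volume_um[1], x$volume_um[2], x$volume_um[3],
    length(x$filaments), x$realized_fill, x$fill_fraction_target
  ))
  invisible(x)
}

# 2D FFT convolution with a kernel given on the same grid, kernel centred.
fft_convolve2d <- function(img, kernel) {
  stopifnot(all(dim(img) == dim(kernel)))
  n <- prod(dim(img))
  # shift kernel centre to [1, 1]
  ci <- floor(dim(kernel) / 2) + 1
  k <- kernel
  k <- k[c(ci[1]:nrow(k), if (ci[1] > 1) 1:(ci[1] - 1)), ]
  k <- k[, c(ci[2]:ncol(k), if (ci[2] > 1) 1:(ci[2] - 1))]
  Re(stats::fft(stats::fft(img) * stats::fft(k), inverse = TRUE)) / n
}

gaussian_kernel2d <- function(nr, nc, sigma_px) {
  r <- seq_len(nr) - (floor(nr / 2) + 1)
  c <- seq_len(nc) - (floor(nc / 2) + 1)
  k <- exp(-outer(r^2, c^2, `+`) / (2 * sigma_px^2))
  k / sum(k)
}

# Low-frequency multiplicative background texture. Centred on its median so
# that the modal (most abundant) background level stays at 1: the
# histogram-mode background estimator then tracks the mean background model
# rather than whichever texture level happens to cover the most area.
background_texture <- function(nr, nc, pixel_size_um, corr_um, sd_rel) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  sm <- fft_convolve2d(noise, gaussian_kernel2d(nr, nc, corr_um / pixel_size_um))
  sm <- (sm - stats::median(sm)) / stats::sd(sm)
  pmax(1 + sd_rel * sm, 0.05)
}

render_one_order <- function(scene, beam, medium, m, depths_um, powers,
                             pixel_size_um) {
  a <- beam$refractive_index * rayleigh_length(beam)
  nz <- dim(scene$density)[1]
  ny <- dim(scene$density)[2]
  nx <- dim(scene$density)[3]
  sig_model <- focal_signal(depths_um, beam, medium, m)
  bg_model <- background_signal(pmax(depths_um, 1e-9), beam, medium, m)
  # lateral excitation kernel of I^m at the focal plane
  sigma_px <- beam$waist_um / (2 * sqrt(m)) / pixel_size_um
  kern <- gaussian_kernel2d(ny, nx, sigma_px)
  # axial weights over scene planes (normalised m-photon on-axis profile)
  halfwin <- ceiling(3 * a / scene$voxel_um)
  bg_scale <- scene$realized_fill / medium$fill_fraction

  lapply(seq_along(depths_um), function(i) {
    d <- depths_um[i]
    zi <- round(d / scene$voxel_um + 0.5)
    zwin <- max(1, zi - halfwin):min(nz, zi + halfwin)
    wts <- (1 + (((zwin - 0.5) * scene$voxel_um - d) / a)^2)^(-m)
    wts <- wts / sum(wts)
    plane <- matrix(0, ny, nx)
    for (j in seq_along(zwin)) plane <- plane + wts[j] * scene$density[zwin[j], , ]
    infocus <- fft_convolve2d(plane, kern)
    pm <- powers[i]^m
    list(
      infocus = infocus * sig_model[i] * pm,
      bg_mean = bg_model[i] * bg_scale * pm,
      sig_model = sig_model[i] * pm,
      bg_model = bg_model[i] * bg_scale * pm
    )
  })
}

#' Render a filament scene into a synthetic z-stack
#'
#' The forward model behind the synthetic phantoms. For each slice at depth
#' d below the surface, an in-focus term (the scene occupancy convolved
#' with the lateral m-photon PSF and weighted by the on-axis axial
#' excitation profile) is scaled by the focal-signal model, an out-of-focus
#' background term (a slowly varying multiplicative texture) is scaled by
#' the background model, and detector counts are formed as
#' `offset + Poisson(photon_scale * total) + Gaussian read noise`, clipped
#' to 16 bit. The green channel is rendered as a weighted sum of an m = 2
#' and an m = 3 pathway (weights from [green_channel_weights()]).
#'
#' @param scene A [generate_filament_scene()] scene.
#' @param beam A [beam_parameters()] object.
#' @param medium A [medium_properties()] object (its fill fraction should
#'   match the scene's for a self-consistent render).
#' @param channel `"blue"` (m = 3), `"red"` (m = 2) or `"green"` (mixed).
#' @param z_step_um Slice spacing of the rendered stack.
#' @param powers Optional per-slice relative surface powers (default:
#'   constant 1).
#' @param detector_offset Constant detector offset in counts.
#' @param photon_scale Counts per unit modelled signal; `NULL` (default)
#'   auto-calibrates so the top-slice in-focus amplitude is ~50 counts,
#'   placing top-slice signal-to-background in the 20:1-100:1 regime.
#' @param read_noise_sd Gaussian read-noise standard deviation in counts.
#' @param bg_texture_corr_um Correlation length of the background texture.
#' @param bg_texture_sd Relative amplitude of the background texture.
#' @param seed Integer seed (full determinism).
#' @return An [image_stack()]; attributes `ground_truth` (the noiseless
#'   expected counts), `model` (a tibble of the per-slice modelled signal
#'   and background) and `clipped` (whether any voxel hit 16-bit
#'   saturation).
#' @export
render_stack <- function(scene, beam, medium,
                         channel = c("blue", "red", "green"),
                         z_step_um = 10,
                         powers = NULL,
                         detector_offset = 100,
                         photon_scale = NULL,
                         read_noise_sd = 2,
                         bg_texture_corr_um = 10,
                         bg_texture_sd = 0.15,
                         seed = 1) {
  stopifnot(inherits(scene, "filament_scene"),
            inherits(beam, "beam_parameters"),
            inherits(medium, "medium_properties"))
  channel <- match.arg(channel)
  ny <- dim(scene$density)[2]
  nx <- dim(scene$density)[3]
  depths_um <- seq(0, scene$volume_um[3] - scene$voxel_um, by = z_step_um)
  n_slices <- length(depths_um)
  if (is.null(powers)) powers <- rep(1, n_slices)
  if (length(powers) != n_slices) {
    stop(sprintf("`powers` must have one entry per slice (%d)", n_slices),
         call. = FALSE)
  }

  orders <- switch(channel, blue = 3, red = 2, green = c(2, 3))
  weights <- if (channel == "green") green_channel_weights() else 1

  parts <- lapply(orders, function(m) {
    render_one_order(scene, beam, medium, m, depths_um, powers, scene$voxel_um)
  })

  # auto-calibrate counts so the shallow in-focus amplitude is ~50
  top_sig <- sum(unlist(lapply(seq_along(orders), function(k) {
    weights[k] * parts[[k]][[1]]$sig_model
  })))
  if (is.null(photon_scale)) photon_scale <- 50 / top_sig

  voxels <- array(0, dim = c(n_slices, ny, nx))
  truth <- array(0, dim = c(n_slices, ny, nx))
  model_rows <- vector("list", n_slices)

  withr::with_seed(seed, {
    for (i in seq_len(n_slices)) {
      # inhomogeneities decorrelate between slices (z steps exceed the
      # lateral correlation length), so each slice draws its own field
      texture <- background_texture(ny, nx, scene$voxel_um, bg_texture_corr_um,
                                    bg_texture_sd)
      total <- matrix(0, ny, nx)
      sig_i <- 0
      bg_i <- 0
      for (k in seq_along(orders)) {
        p <- parts[[k]][[i]]
        total <- total + weights[k] * (p$infocus + p$bg_mean * texture)
        sig_i <- sig_i + weights[k] * p$sig_model
        bg_i <- bg_i + weights[k] * p$bg_model
      }
      lambda <- pmax(photon_scale * total, 0) # FFT ringing can leave tiny negatives
      counts <- detector_offset + stats::rpois(length(lambda), lambda) +
        round(stats::rnorm(length(lambda), 0, read_noise_sd))
      voxels[i, , ] <- matrix(pmin(pmax(counts, 0), 65535), ny, nx)
      truth[i, , ] <- detector_offset + lambda
      model_rows[[i]] <- tibble::tibble(
        slice = i, depth_um = depths_um[i],
        model_signal = photon_scale * sig_i,
        model_background = photon_scale * bg_i,
        model_ratio = ifelse(bg_i > 0, sig_i / bg_i, Inf)
      )
    }
  })

  out <- image_stack(voxels, z_step_um, scene$voxel_um, channel = channel,
                     powers = powers)
  attr(out, "ground_truth") <- truth
  attr(out, "model") <- dplyr::bind_rows(model_rows)
  attr(out, "photon_scale") <- photon_scale
  attr(out, "clipped") <- any(voxels == 65535)
  out
}

#' Render a synthetic bead stack for PSF measurement
#'
#' Places a single uniformly fluorescent sphere at the centre of a small
#' volume and renders it through the m-photon excitation PSF by exact 3D
#' convolution on a fine grid, then samples slices at the acquisition
#' z-step and adds detector noise. Used for render-and-fit round trips with
#' [fit_psf_radii()].
#'
#' @param beam A [beam_parameters()] object.
#' @param order Photon order m (2 or 3).
#' @param bead_diameter_um Bead diameter (default 0.5).
#' @param z_step_um Acquisition slice spacing (default 0.25).
#' @param pixel_size_um Lateral pixel size (default 0.05).
#' @param lateral_halfwidth_um,axial_halfwidth_um Rendered half-extents.
#' @param peak_counts Expected counts at the profile peak above offset.
#' @param detector_offset Detector offset in counts.
#' @param read_noise_sd Gaussian read noise (counts); set 0 with
#'   `shot_noise = FALSE` for a noiseless render.
#' @param shot_noise Apply Poisson shot noise?
#' @param seed Integer seed.
#' @return An [image_stack()].
#' @export
generate_bead_stack <- function(beam, order = 3,
                                bead_diameter_um = 0.5,
                                z_step_um = 0.25,
                                pixel_size_um = 0.05,
                                lateral_halfwidth_um = 1.6,
                                axial_halfwidth_um = 3.0,
                                peak_counts = 3000,
                                detector_offset = 100,
                                read_noise_sd = 2,
                                shot_noise = TRUE,
                                seed = 1) {
  stopifnot(inherits(beam, "beam_parameters"))
  m <- check_order(order)
  if (bead_diameter_um < 0) stop("`bead_diameter_um` must be >= 0", call. = FALSE)
  if (bead_diameter_um > min(lateral_halfwidth_um, axial_halfwidth_um)) {
    stop("bead does not fit the rendered volume", call. = FALSE)
  }

  xs <- seq(-lateral_halfwidth_um, lateral_halfwidth_um, by = pixel_size_um)
  # fine axial grid for the convolution; output slices subsample it
  sub <- max(1L, round(z_step_um / pixel_size_um))
  dz_fine <- z_step_um / sub
  zs <- seq(-axial_halfwidth_um, axial_halfwidth_um, by = dz_fine)
  nx <- length(xs)
  nz <- length(zs)

  w2 <- beam_waist(zs, beam)^2
  ax <- (beam$waist_um^2 / w2)^m # on-axis m-photon profile per z
  lat <- lapply(seq_len(nz), function(iz) {
    exp(-2 * m * outer(xs^2, xs^2, `+`) / w2[iz])
  })
  exc <- array(0, dim = c(nz, nx, nx))
  for (iz in seq_len(nz)) exc[iz, , ] <- ax[iz] * lat[[iz]]

  if (bead_diameter_um > 0) {
    R <- bead_diameter_um / 2
    ball <- array(0, dim = c(nz, nx, nx))
    r2 <- outer(xs^2, xs^2, `+`)
    for (iz in seq_len(nz)) {
      if (abs(zs[iz]) <= R) ball[iz, , ] <- (r2 + zs[iz]^2 <= R^2) * 1
    }
    # circularly shift the ball centre to index [1, 1, 1]
    ci <- c(which.min(abs(zs)), which.min(abs(xs)), which.min(abs(xs)))
    ball <- ball[c(ci[1]:nz, if (ci[1] > 1) 1:(ci[1] - 1)), , ]
    ball <- ball[, c(ci[2]:nx, if (ci[2] > 1) 1:(ci[2] - 1)), ]
    ball <- ball[, , c(ci[3]:nx, if (ci[3] > 1) 1:(ci[3] - 1))]
    exc <- Re(stats::fft(stats::fft(exc) * stats::fft(ball), inverse = TRUE)) /
      length(exc)
    exc[exc < 0] <- 0
  }

  keep <- seq(1, nz, by = sub)
  exc <- exc[keep, , ]
  expected <- detector_offset + peak_counts * exc / max(exc)

  counts <- withr::with_seed(seed, {
    lam <- if (shot_noise) stats::rpois(length(expected), expected) else round(expected)
    lam + round(stats::rnorm(length(expected), 0, read_noise_sd))
  })
  voxels <- array(pmin(pmax(counts, 0), 65535), dim = dim(expected))

  image_stack(voxels, z_step_um, pixel_size_um)
}
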