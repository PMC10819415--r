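# Shared fixtures and independent oracles used across the test files.

default_beam <- beam_parameters(wavelength_um = 1.040, waist_um = 0.55,
                                refractive_index = 1.33)

# Independent background oracle: trapezoid quadrature in (r, z) with the
# lateral integral done numerically (the implementation uses the analytic
# lateral Gaussian integral, so the lateral treatment is independent).
oracle_background <- function(depth_um, beam, medium, m, nz = 4000, nr = 600,
                              z_from = 5.8) {
  w0 <- beam$waist_um
  a <- beam$refractive_index * pi * w0^2 / beam$wavelength_um
  le <- medium$scattering_length_um
  La <- medium$absorption_length_um
  zs <- seq(z_from, depth_um, length.out = nz)
  vals <- vapply(zs, function(z) {
    w <- w0 * sqrt(1 + (z / a)^2)
    rmax <- 4 * w / sqrt(m)
    rs <- seq(0, rmax, length.out = nr)
    f <- ((w0^2 / w^2) * exp(-2 * rs^2 / w^2))^m * 2 * pi * rs
    lat <- sum((f[-1] + f[-nr]) / 2) * (rs[2] - rs[1])
    lat * exp(-m * (depth_um - z) / le) * exp(-(depth_um - z) / La)
  }, numeric(1))
  h <- zs[2] - zs[1]
  sum((vals[-1] + vals[-nz]) / 2) * h
}

# Independent focal oracle: brute-force Monte-Carlo integration of I^m over
# the focal volume (uniform sampling of a bounding box).
mc_focal <- function(depth_um, beam, medium, m, nsamp = 4e6, seed = 11) {
  w0 <- beam$waist_um
  a <- beam$refractive_index * pi * w0^2 / beam$wavelength_um
  le <- medium$scattering_length_um
  withr::with_seed(seed, {
    L <- 4 * w0 * sqrt(1 + (5.8 / a)^2) / sqrt(m)
    x <- stats::runif(nsamp, -L, L)
    y <- stats::runif(nsamp, -L, L)
    z <- stats::runif(nsamp, -5.8, 5.8)
    w2 <- w0^2 * (1 + (z / a)^2)
    I <- (w0^2 / w2) * exp(-2 * (x^2 + y^2) / w2) * exp(-(depth_um - z) / le)
    mean(I^m) * (2 * L)^2 * 11.6
  })
}

# Independent bead-convolution oracle for the lateral profile: analytic
# radial Gaussian-disk convolution per z-offset (Bessel integral) instead
# of a 3D grid sum.
oracle_bead_lateral_radius <- function(beam, m, bead_diameter_um) {
  w0 <- beam$waist_um
  a <- beam$refractive_index * pi * w0^2 / beam$wavelength_um
  R <- bead_diameter_um / 2

  gauss_disk <- function(x, w, rho_max) {
    c0 <- 2 * m / w^2
    f <- function(rho) {
      t <- 2 * c0 * x * rho
      exp(-c0 * (x - rho)^2) * besselI(t, 0, expon.scaled = TRUE) * 2 * pi * rho
    }
    stats::integrate(f, 0, rho_max, rel.tol = 1e-9)$value
  }
  profile_at <- function(x) {
    stats::integrate(Vectorize(function(zp) {
      w <- w0 * sqrt(1 + (zp / a)^2)
      (w0^2 / w^2)^m * gauss_disk(x, w, sqrt(R^2 - zp^2))
    }), -R, R, rel.tol = 1e-7)$value
  }
  peak <- profile_at(0)
  stats::uniroot(function(x) profile_at(x) / peak - exp(-2),
                 c(w0 / sqrt(m) / 2, w0 / sqrt(m) + R), tol = 1e-5)$root
}

# Small cached fixtures so expensive renders are built once per run.
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

closed_loop_stack <- function() {
  fixture("closed_loop", function() {
    scene <- generate_filament_scene(volume_um = c(32, 32, 330),
                                     voxel_um = 0.5, seed = 1)
    medium <- medium_properties(80, 500, fill_fraction = scene$realized_fill)
    depths <- seq(0, 330 - 0.5, by = 15)
    powers <- exp(depths / 80)
    st0 <- render_stack(scene, default_beam, medium, channel = "red",
                        z_step_um = 15, powers = powers, seed = 2)
    stack <- render_stack(scene, default_beam, medium, channel = "red",
                          z_step_um = 15, powers = powers,
                          photon_scale = attr(st0, "photon_scale") * 40,
                          seed = 2)
    list(scene = scene, medium = medium, stack = stack)
  })
}
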