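test_that("Rayleigh length follows pi w0^2 / lambda", {
  expect_equal(rayleigh_length(beam_parameters(wavelength_um = 1.040,
                                               waist_um = 0.55)),
               pi * 0.55^2 / 1.040, tolerance = 1e-12)
  expect_equal(rayleigh_length(beam_parameters(wavelength_um = 1.040,
                                               waist_um = 0.55)),
               0.914, tolerance = 1e-3)
  # quadratic in the waist, identity case
  expect_equal(
    rayleigh_length(beam_parameters(waist_um = 1.1)),
    4 * rayleigh_length(beam_parameters(waist_um = 0.55))
  )
  expect_equal(rayleigh_length(beam_parameters(wavelength_um = pi, waist_um = 1)), 1)
})

test_that("beam waist is even in z and hits sqrt(2) w0 at the in-medium Rayleigh length", {
  beam <- default_beam
  expect_equal(beam_waist(0, beam), beam$waist_um)
  a <- beam$refractive_index * rayleigh_length(beam)
  expect_equal(beam_waist(a, beam), beam$waist_um * sqrt(2), tolerance = 1e-12)
  zs <- c(0.3, 1.7, 5, 42)
  expect_equal(beam_waist(zs, beam), beam_waist(-zs, beam))
  # frozen arithmetic oracle: 0.55 * sqrt(1 + (5 / (1.33 * 0.9137806))^2)
  expect_equal(beam_waist(5, beam), 2.328647, tolerance = 1e-6)
})

test_that("beam intensity is normalised, Gaussian laterally, and even in x and y", {
  beam <- default_beam
  expect_equal(beam_intensity(0, 0, 0, beam), 1)
  a <- beam$refractive_index * rayleigh_length(beam)
  expect_equal(beam_intensity(0, 0, a, beam), 0.5, tolerance = 1e-12)
  # at lateral distance w(z) the intensity is e^-2 of the on-axis value
  for (z in c(0, 2, 7)) {
    w <- beam_waist(z, beam)
    expect_equal(beam_intensity(w, 0, z, beam),
                 exp(-2) * beam_intensity(0, 0, z, beam))
  }
  expect_equal(beam_intensity(1.2, -0.7, 3, beam),
               beam_intensity(-1.2, 0.7, 3, beam))
  # ballistic loss grows toward the surface (positive z)
  expect_equal(beam_intensity(0, 0, 60, beam, scattering_length_um = 120) /
                 beam_intensity(0, 0, 60, beam),
               exp(0.5), tolerance = 1e-12)
  expect_error(beam_intensity(0, 0, 0, beam, scattering_length_um = -1),
               "scattering_length_um")
})

test_that("lateral power is conserved up to the ballistic loss factor", {
  beam <- default_beam
  for (z in c(0, 3, 10)) {
    for (le in c(Inf, 120)) {
      got <- stats::integrate(
        Vectorize(function(r) beam_intensity(r, 0, z, beam, le) * 2 * pi * r),
        0, Inf, rel.tol = 1e-10
      )$value
      want <- pi * beam$waist_um^2 / 2 * (if (is.finite(le)) exp(z / le) else 1)
      expect_equal(got, want, tolerance = 1e-7)
    }
  }
})

test_that("excitation density is the m-th power of intensity", {
  expect_equal(excitation_density(1, 3), 1)
  expect_equal(excitation_density(0.5, 3), 0.125)
  expect_equal(excitation_density(0.5, 2), 0.25)
  # multiplicative and monotone
  I <- seq(0.1, 1, 0.1)
  expect_equal(excitation_density(2 * I, 3), 8 * excitation_density(I, 3))
  expect_true(all(diff(excitation_density(I, 2)) > 0))
  expect_error(excitation_density(0.5, 4), "order")
})

test_that("m-photon lateral PSF radii reproduce the measured 2P/3P values", {
  beam <- default_beam
  expect_equal(round(psf_lateral_radius(beam, 3), 2), 0.32)
  expect_equal(round(psf_lateral_radius(beam, 2), 2), 0.39)
  expect_equal(psf_lateral_radius(beam, 1), beam$waist_um)
  # ordering holds for any waist
  for (w0 in c(0.3, 0.55, 1.2)) {
    b <- beam_parameters(waist_um = w0)
    expect_true(psf_lateral_radius(b, 3) < psf_lateral_radius(b, 2))
    expect_true(psf_lateral_radius(b, 2) < w0)
  }
})

test_that("diffraction-limited waist is 0.41 lambda / NA", {
  expect_equal(round(diffraction_limited_waist(1.040, 1.05), 1), 0.4)
  expect_equal(diffraction_limited_waist(1, 0.41), 1)
  expect_equal(diffraction_limited_waist(1.040, 0.5),
               2 * diffraction_limited_waist(1.040, 1.0))
  expect_error(diffraction_limited_waist(1.040, 0), "na")
})

test_that("bead convolution widens the PSF and matches an independent oracle", {
  beam <- default_beam
  # zero diameter reduces to the unconvolved radii
  p0 <- psf_with_bead(beam, 3, 0)
  expect_equal(p0$lateral_radius_um, psf_lateral_radius(beam, 3))
  # strictly wider for a finite bead
  p <- psf_with_bead(beam, 3, 0.5)
  expect_gt(p$lateral_radius_um, psf_lateral_radius(beam, 3))
  expect_gt(p$axial_radius_um, p0$axial_radius_um)
  # independent Bessel-integral oracle for the lateral radius
  oracle <- oracle_bead_lateral_radius(beam, 3, 0.5)
  expect_equal(p$lateral_radius_um, oracle, tolerance = 0.01)
  expect_error(psf_with_bead(beam, 3, -0.1), "bead_diameter_um")
})
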