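test_that("focal signal obeys the closed-form loss factors", {
  beam <- default_beam
  # lossless medium: no depth dependence
  med0 <- medium_properties(Inf, Inf, fill_fraction = 1)
  s <- focal_signal(c(0, 200, 900), beam, med0, 3)
  expect_equal(s[2], s[1])
  expect_equal(s[3], s[1])
  # with losses: focal(d)/focal(0) = exp(-m d / le) * exp(-d / La)
  med <- medium_properties(120, 500, fill_fraction = 1)
  for (m in c(2, 3)) {
    ratio <- focal_signal(300, beam, med, m) / focal_signal(0, beam, med, m)
    expect_equal(ratio, exp(-m * 300 / 120) * exp(-300 / 500), tolerance = 1e-6)
  }
  # the 1/fill focal boost
  med_half <- medium_properties(120, 500, fill_fraction = 0.05)
  med_full <- medium_properties(120, 500, fill_fraction = 0.10)
  expect_equal(focal_signal(100, beam, med_half, 3),
               2 * focal_signal(100, beam, med_full, 3))
  expect_error(focal_signal(-5, beam, med, 3), "non-negative")
})

test_that("background is zero inside the focal window and accumulates with depth", {
  beam <- default_beam
  med <- medium_properties(120, 500, fill_fraction = 1)
  expect_equal(background_signal(c(1, 5.8), beam, med, 3), c(0, 0))
  d <- seq(10, 600, by = 30)
  bg <- background_signal(d, beam, med, 3)
  expect_true(all(bg > 0))
  # in focus-referenced units (undoing the fixed-surface-power ballistic
  # prefactor) the integration domain only grows, so the integral does too
  med_noabs <- medium_properties(120, Inf, fill_fraction = 1)
  accum <- background_signal(d, beam, med_noabs, 3) * exp(3 * d / 120)
  expect_true(all(diff(accum) > 0))
  expect_error(background_signal(0, beam, med, 3), "positive")
})

test_that("focal and background integrals agree with independent oracles", {
  beam <- default_beam
  # background: trapezoid (r, z) quadrature with numeric lateral integral
  grid <- expand.grid(depth = c(200, 400), le = c(80, 120), m = c(2, 3))
  for (i in seq_len(nrow(grid))) {
    med <- medium_properties(grid$le[i], 500, fill_fraction = 1)
    impl <- background_signal(grid$depth[i], beam, med, grid$m[i])
    ora <- oracle_background(grid$depth[i], beam, med, grid$m[i])
    expect_equal(impl, ora, tolerance = 0.005)
  }
  # focal: brute-force Monte-Carlo integration of I^m over the focal box
  med <- medium_properties(120, Inf, fill_fraction = 1)
  impl <- focal_signal(300, beam, med, 3)
  expect_equal(impl, mc_focal(300, beam, med, 3), tolerance = 0.02)
})

test_that("SBR is infinite at shallow depth, 3P beats 2P, and scales as 1/fill", {
  beam <- default_beam
  med <- medium_properties(120, 500, fill_fraction = 0.1)
  expect_equal(sbr(3, beam, med, 3)$ratio, Inf)
  for (d in c(100, 300, 500)) {
    expect_gte(sbr(d, beam, med, 3)$ratio, sbr(d, beam, med, 2)$ratio)
  }
  med2 <- medium_properties(120, 500, fill_fraction = 0.2)
  expect_equal(sbr(250, beam, med, 3)$ratio,
               2 * sbr(250, beam, med2, 3)$ratio, tolerance = 1e-9)
})

test_that("depth_at_sbr solves the crossing and is monotone in the target", {
  beam <- default_beam
  med <- medium_properties(120, 500, fill_fraction = 1)
  d1 <- depth_at_sbr(1, beam, med, 3)
  expect_equal(sbr(d1, beam, med, 3)$ratio, 1, tolerance = 0.05)
  d10 <- depth_at_sbr(10, beam, med, 3)
  expect_gt(d1, d10)
  # lossless medium never crosses a low target
  med0 <- medium_properties(Inf, Inf, fill_fraction = 1)
  expect_error(depth_at_sbr(1e-3, beam, med0, 3), "does not cross")
})

test_that("depth limit grows superlinearly with the scattering length", {
  beam <- default_beam
  mk <- function(le) medium_properties(le, 500, fill_fraction = 1)
  d60 <- depth_at_sbr(1, beam, mk(60), 3)
  d120 <- depth_at_sbr(1, beam, mk(120), 3)
  d200 <- depth_at_sbr(1, beam, mk(200), 3, bracket = c(12, 3000))
  expect_gt(d120 / d60, 2)
  expect_gt(d200 / d120, 200 / 120)
})

test_that("with no absorption the ratio rescales with (depth, le) as the fixed-focus scaling predicts", {
  beam <- default_beam
  mk <- function(le) medium_properties(le, Inf, fill_fraction = 1)
  # two-photon background is surface-dominated early: k^(2m-3) = k
  r1 <- sbr(400, beam, mk(80), 2)$ratio
  r2 <- sbr(800, beam, mk(160), 2)$ratio
  expect_equal(r2 / r1, 2, tolerance = 0.05)
  # three-photon reaches the same regime deeper: k^(2m-3) = k^3
  r1 <- sbr(8 * 80, beam, mk(80), 3)$ratio
  r2 <- sbr(8 * 160, beam, mk(160), 3)$ratio
  expect_equal(r2 / r1, 8, tolerance = 0.02)
})

test_that("sbr_map is monotone along both axes and 3P dominates 2P", {
  beam <- default_beam
  med <- medium_properties(100, 500, fill_fraction = 0.1)
  depths <- seq(20, 620, by = 100)
  les <- c(60, 100, 160)
  m3 <- sbr_map(depths, les, beam, med, 3)
  m2 <- sbr_map(depths, les, beam, med, 2)
  expect_s3_class(m3, "sbr_map")
  wide3 <- tidyr::pivot_wider(m3[, c("scattering_length_um", "depth_um", "ratio")],
                              names_from = "depth_um", values_from = "ratio")
  mat3 <- as.matrix(wide3[, -1])
  # each row (fixed le): non-increasing with depth beyond twice the focal window
  expect_true(all(apply(mat3, 1, function(r) all(diff(r) <= 0))))
  # each column (fixed depth): non-decreasing with le
  expect_true(all(apply(mat3, 2, function(c) all(diff(c) >= 0))))
  expect_true(all(m3$ratio >= m2$ratio))
  expect_equal(attr(m3, "contour_levels"), sbr_contour_levels())
})
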