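test_that("filament scenes hit the target fill and are deterministic", {
  sc <- generate_filament_scene(volume_um = c(20, 20, 20), seed = 1)
  expect_gte(sc$realized_fill, 0.08)
  expect_lte(sc$realized_fill, 0.12)
  sc2 <- generate_filament_scene(volume_um = c(20, 20, 20), seed = 1)
  expect_identical(sc$density, sc2$density)
  # doubling the target roughly doubles the occupied voxel count
  dense <- generate_filament_scene(volume_um = c(20, 20, 20),
                                   fill_fraction = 0.2, seed = 1)
  ratio <- sum(dense$density > 0) / sum(sc$density > 0)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
  expect_error(generate_filament_scene(volume_um = c(1, 20, 20)),
               "4 filament radii")
})

test_that("an empty scene renders to offset plus noise", {
  sc <- generate_filament_scene(volume_um = c(16, 16, 60), seed = 2)
  sc$density[] <- 0 # strip the filaments, keep the geometry
  med <- medium_properties(Inf, Inf, fill_fraction = 0.1)
  st <- render_stack(sc, default_beam, med, channel = "blue", z_step_um = 20,
                     photon_scale = 1, detector_offset = 130, seed = 3)
  for (i in seq_len(dim(st$voxels)[1])) {
    expect_equal(background_level(st$voxels[i, , ]), 130, tolerance = 0.02)
  }
})

test_that("a lossless render has depth-independent in-focus signal", {
  sc <- generate_filament_scene(volume_um = c(16, 16, 80), seed = 4)
  med <- medium_properties(Inf, Inf, fill_fraction = sc$realized_fill)
  st <- render_stack(sc, default_beam, med, channel = "blue", z_step_um = 20,
                     seed = 5)
  mo <- attr(st, "model")
  expect_equal(mo$model_signal, rep(mo$model_signal[1], nrow(mo)))
  # measured per-slice signal varies only with the scene, not with depth
  pr <- sbr_profile(st, threshold_config("brighter_fraction", 0.01))
  expect_lt(diff(range(pr$signal)) / stats::median(pr$signal), 0.5)
})

test_that("rendered stacks keep the histogram mode at the detector offset when background is negligible", {
  sc <- generate_filament_scene(volume_um = c(24, 24, 40), seed = 6)
  med <- medium_properties(170, 500, fill_fraction = sc$realized_fill)
  st <- render_stack(sc, default_beam, med, channel = "blue", z_step_um = 20,
                     detector_offset = 100, seed = 7)
  expect_lte(abs(background_level(st$voxels[1, , ]) - 100), 3)
})

test_that("renders are fully deterministic under a fixed seed", {
  sc <- generate_filament_scene(volume_um = c(16, 16, 40), seed = 8)
  med <- medium_properties(120, 500, fill_fraction = sc$realized_fill)
  a <- render_stack(sc, default_beam, med, channel = "green", z_step_um = 20,
                    seed = 9)
  b <- render_stack(sc, default_beam, med, channel = "green", z_step_um = 20,
                    seed = 9)
  expect_identical(a$voxels, b$voxels)
  c <- render_stack(sc, default_beam, med, channel = "green", z_step_um = 20,
                    seed = 10)
  expect_false(identical(a$voxels, c$voxels))
})

test_that("the extracted signal tracks the rendered ground-truth amplitude", {
  cl <- closed_loop_stack()
  st <- cl$stack
  truth <- attr(st, "ground_truth")
  cfg <- threshold_config("brighter_fraction", 0.002)
  for (i in c(2, 8, 15)) {
    measured <- signal_level(st$voxels[i, , ], cfg)$signal
    truth_amp <- stats::quantile(truth[i, , ], 0.998) -
      background_level(round(truth[i, , ]))
    expect_equal(measured, as.numeric(truth_amp), tolerance = 0.15)
  }
})

test_that("power series are deterministic and exact without noise", {
  clean <- generate_power_series(noise_cv = 0, seed = 1)
  blue <- dplyr::filter(clean, channel == "blue")
  expect_equal(blue$signal, blue$power^3.09)
  a <- generate_power_series(seed = 7)
  b <- generate_power_series(seed = 7)
  expect_identical(a, b)
  # a channel's draw does not depend on which other channels are requested
  solo <- generate_power_series("red", seed = 7)
  expect_equal(dplyr::filter(a, channel == "red")$signal, solo$signal)
})

test_that("the green channel mixes m = 2 and m = 3 pathways to a 2.81 net slope", {
  w <- green_channel_weights()
  expect_equal(sum(w), 1)
  clean <- generate_power_series("green", noise_cv = 0, seed = 1)
  expect_equal(clean$signal, w[["m2"]] * clean$power^2 + w[["m3"]] * clean$power^3)
  expect_equal(fit_power_exponent(clean)$exponent, 2.81, tolerance = 1e-6)
})

test_that("power schedules are exact exponentials with flagged truncation", {
  sched <- generate_power_schedule(le_um = 170, noise_cv = 0, seed = 1)
  expect_equal(sched$power, exp(sched$depth_um / 170))
  expect_equal(estimate_attenuation_length(sched)$le_um, 170, tolerance = 1e-9)
  capped <- generate_power_schedule(le_um = 170, noise_cv = 0, max_power = 5,
                                    seed = 1)
  expect_true(any(capped$truncated))
  expect_lte(max(capped$power), 5)
  expect_identical(generate_power_schedule(seed = 3),
                   generate_power_schedule(seed = 3))
})

test_that("analysing a rendered stack reproduces the model SBR within a factor of two", {
  cl <- closed_loop_stack()
  pr <- sbr_profile(cl$stack, threshold_config("brighter_fraction", 0.002))
  mo <- attr(cl$stack, "model")
  cmp <- dplyr::inner_join(pr, mo, by = c("slice", "depth_um"))
  # compare where the modelled background is detectable (> 5 counts)
  cmp <- dplyr::filter(cmp, model_background > 5)
  expect_gte(nrow(cmp), 15)
  expect_true(all(cmp$ratio / cmp$model_ratio > 0.5))
  expect_true(all(cmp$ratio / cmp$model_ratio < 2))
})
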