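test_that("zero-density fields are empty and placement honors density", {
  p0 <- pillar_field_params(density_per_um2 = 0, height_mean_nm = 400,
                            height_sd_nm = 50, tip_diameter_mean_nm = 50,
                            tip_diameter_sd_nm = 5)
  expect_identical(nrow(sample_pillar_field(p0, seed = 1)), 0L)

  # densest surface type: ~137 per um2; recovered density within Poisson
  # sampling error of the target over a 3 x 3 um field
  p <- surface_preset("pe-ns-short", field_size_um = c(3, 3))
  f <- sample_pillar_field(p, seed = 42)
  lambda <- 137 * 9
  expect_lt(abs(nrow(f) - lambda), 3 * sqrt(lambda))
  expect_equal(characterize_field(f, 9)$density_per_um2, nrow(f) / 9)
  # aligned preset: all axes vertical
  expect_true(all(f$axis_y == 1))
  # hard-core spacing respected
  d2 <- as.matrix(dist(f[, c("base_x_nm", "base_z_nm")]))
  diag(d2) <- Inf
  expect_gte(min(d2), p$min_spacing_nm)
})

test_that("sampled pillar dimensions track the preset distributions", {
  p <- surface_preset("to-ns-long", field_size_um = c(10, 10))
  f <- sample_pillar_field(p, seed = 3)
  n <- nrow(f)
  expect_lt(abs(mean(f$height_nm) - 1700), 3 * 347 / sqrt(n))
  expect_lt(abs(mean(f$tip_diameter_nm) - 114), 3 * 26 / sqrt(n))
  expect_true(all(f$height_nm > 0 & f$tip_diameter_nm > 0))
  expect_true(all(f$tip_diameter_nm <= f$base_diameter_nm))
  # random orientation: unit axes, tilt bounded
  nrm <- sqrt(f$axis_x^2 + f$axis_y^2 + f$axis_z^2)
  expect_equal(nrm, rep(1, n), tolerance = 1e-12)
  expect_true(all(acos(pmin(f$axis_y, 1)) <= p$max_tilt_deg * pi / 180 + 1e-9))
})

test_that("unsatisfiable hard-core packing fails loudly", {
  p <- pillar_field_params(density_per_um2 = 200, height_mean_nm = 100,
                           height_sd_nm = 0, tip_diameter_mean_nm = 50,
                           tip_diameter_sd_nm = 0,
                           field_size_um = c(1, 1), min_spacing_nm = 120)
  expect_error(sample_pillar_field(p, seed = 1), "placement failed")
})

test_that("field sampling is deterministic in (params, seed)", {
  p <- surface_preset("ah-ns-medium", field_size_um = c(2, 2))
  expect_identical(sample_pillar_field(p, seed = 5),
                   sample_pillar_field(p, seed = 5))
  expect_false(identical(sample_pillar_field(p, seed = 5),
                         sample_pillar_field(p, seed = 6)))
})

test_that("cell shapes carry exact analytic morphometrics", {
  cocc <- cell_shape("coccus", width_nm = 1000)
  expect_equal(cocc$volume_um3, 0.5236, tolerance = 1e-4)
  expect_equal(cocc$surface_area_um2, 3.1416, tolerance = 1e-4)

  rod <- cell_shape("rod", width_nm = 500, length_nm = 2000)
  expect_equal(rod$volume_um3, 0.3599, tolerance = 1e-3)
  expect_equal(rod$surface_area_um2,
               (2 * pi * 250 * 1500 + 4 * pi * 250^2) / 1e6, tolerance = 1e-9)

  # the abnormally large impeded cell: ~4 um long, ~1 um wide
  big <- cell_shape("rod", width_nm = 1000, length_nm = 4000)
  expect_equal(big$volume_um3,
               (pi * 500^2 * 3000 + 4 / 3 * pi * 500^3) / 1e9, tolerance = 1e-9)

  expect_error(cell_shape("rod", width_nm = 500, length_nm = 400),
               "invalid rod dimensions")
})

test_that("composed scenes realize the intended interactions on the grid", {
  sc <- phantom_scene(preset = "ah-ns-medium", cell_kind = "coccus",
                      interactions = c("penetration", "impedance"),
                      seed = 19)
  gi <- sc$ground_truth$interactions
  pen <- gi[gi$intended_class == "penetration", ]
  voxel <- max(sc$volume$spacing_nm)
  expect_lte(abs(pen$realized_depth_nm - pen$intended_depth_nm), voxel)
  imp <- gi[gi$intended_class == "impedance", ]
  expect_identical(imp$realized_class, "impedance")
  expect_equal(imp$realized_depth_nm, 0)

  # rupture conserves volume: realized = (1 - deficit) x reference within
  # voxelization error
  scr <- phantom_scene(preset = "pe-ns-short", cell_kind = "coccus",
                       interactions = list(list(class = "rupture",
                                                depth_nm = 60,
                                                volume_deficit_fraction = 0.3)),
                       seed = 23)
  gc <- scr$ground_truth$cells[[1]]
  expect_equal(gc$voxel_volume_um3, 0.7 * gc$reference_volume_um3,
               tolerance = 0.02)
})

test_that("contradictory or invalid interaction sets are rejected", {
  cell <- cell_shape("coccus", width_nm = 1000, center_nm = c(1000, 800, 1000))
  pillars <- data.frame(pillar_id = 1L, base_x_nm = 1000, base_z_nm = 1000,
                        axis_x = 0, axis_y = 1, axis_z = 0,
                        height_nm = 400, tip_diameter_nm = 50,
                        base_diameter_nm = 100)
  expect_error(compose_scene(cell, pillars,
                             list(interaction_spec(1, "none"),
                                  interaction_spec(1, "penetration", 50)),
                             measure_realized = FALSE),
               "contradictory")
  expect_error(compose_scene(cell, pillars,
                             list(interaction_spec(9, "none")),
                             measure_realized = FALSE),
               "unknown pillar")
  expect_error(compose_scene(cell, pillars, list(),
                             spacing_nm = c(2, 2, 2),
                             max_voxels = 1e4, measure_realized = FALSE),
               "voxel budget")
  expect_error(interaction_spec(1, "none", depth_nm = 10), "depth_nm")
  expect_error(interaction_spec(1, "penetration", depth_nm = 0), "depth_nm")
})

test_that("scenes and stacks are bit-for-bit reproducible", {
  a <- phantom_scene(preset = "to-ns-short", cell_kind = "rod",
                     interactions = "penetration", seed = 4,
                     measure_realized = FALSE)
  b <- phantom_scene(preset = "to-ns-short", cell_kind = "rod",
                     interactions = "penetration", seed = 4,
                     measure_realized = FALSE)
  expect_identical(a$volume$labels, b$volume$labels)
  acq <- acquisition_params(slice_thickness_nm = 30, pixel_size_nm = 12,
                            drift_sd_px = 2, noise_sd = 8, texture_sd = 5)
  s1 <- simulate_acquisition(a$volume, acq, seed = 9)
  s2 <- simulate_acquisition(b$volume, acq, seed = 9)
  expect_identical(s1$stack$intensities, s2$stack$intensities)
  expect_identical(s1$offsets, s2$offsets)
})

test_that("acquisition distorts the stack as specified", {
  sc <- phantom_scene(preset = "ah-ns-medium", cell_kind = "coccus",
                      interactions = "none", seed = 2,
                      measure_realized = FALSE)
  # tilt 90, no drift/noise: the stack is the grayscale-mapped volume
  acq90 <- acquisition_params(tilt_deg = 90, slice_thickness_nm = 20,
                              pixel_size_nm = 15)
  st90 <- simulate_acquisition(sc$volume, acq90, seed = 1)$stack
  lut <- c(20, 90, 200, 160, 60)
  expect_identical(st90$intensities,
                   array(lut[sc$volume$labels + 1], dim(sc$volume$labels)))

  # tilt 52: vertical extents compress by sin(52 deg) = 0.7880
  acq52 <- acquisition_params(tilt_deg = 52, slice_thickness_nm = 20,
                              pixel_size_nm = 15)
  st52 <- simulate_acquisition(sc$volume, acq52, seed = 1)$stack
  expect_equal(dim(st52$intensities)[1],
               round(dim(sc$volume$labels)[1] * sin(52 * pi / 180)))

  # recorded offsets equal the returned offsets (same draw)
  acqd <- acquisition_params(tilt_deg = 52, slice_thickness_nm = 20,
                             pixel_size_nm = 15, drift_sd_px = 2)
  out <- simulate_acquisition(sc$volume, acqd, seed = 3,
                              ground_truth = sc$ground_truth)
  expect_identical(out$offsets, out$ground_truth$slice_offsets)
  expect_equal(out$offsets[1, ], c(dy = 0, dx = 0))
})
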