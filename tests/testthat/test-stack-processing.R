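test_that("an already-aligned stack registers at zero offset everywhere", {
  ch <- phantom_chain(noise_sd = 0, drift_sd_px = 0, texture_sd = 5)
  al <- align_stack(ch$sim$stack)
  expect_true(all(al$alignment$offsets == 0))
})

test_that("noise-free injected drift is recovered exactly", {
  sc <- phantom_scene(preset = "ah-ns-medium", cell_kind = "coccus",
                      interactions = c("penetration", "none"), seed = 7,
                      measure_realized = FALSE)
  acq <- acquisition_params(tilt_deg = 52, slice_thickness_nm = 20,
                            pixel_size_nm = 15, drift_sd_px = 2,
                            noise_sd = 0, texture_sd = 5)
  sim <- simulate_acquisition(sc$volume, acq, seed = 8)
  al <- align_stack(sim$stack)
  expect_true(any(sim$offsets != 0))
  expect_identical(unname(al$alignment$offsets), unname(sim$offsets))
})

test_that("drift recovery under noise stays within one pixel", {
  ch <- phantom_chain()
  err <- abs(ch$alignment$offsets - ch$sim$offsets)
  expect_gte(mean(apply(err, 1, max) <= 1), 0.95)
})

test_that("all-constant slices get zero offsets and zero confidence", {
  st <- image_stack(array(50, c(32, 32, 4)), pixel_size_nm = 10,
                    slice_thickness_nm = 30)
  al <- align_stack(st)
  expect_true(all(al$alignment$offsets == 0))
  expect_true(all(al$alignment$confidence == 0))
})

test_that("foreshortening correction applies 1/sin(tilt) and is guarded", {
  # tilt 90: identity
  st <- image_stack(array(runif(40 * 40 * 3, 0, 255), c(40, 40, 3)),
                    pixel_size_nm = 10, slice_thickness_nm = 30,
                    tilt_deg = 90, aligned = TRUE)
  out <- correct_foreshortening(st)
  expect_identical(out$intensities, st$intensities)
  expect_true(out$foreshortening_corrected)
  expect_error(correct_foreshortening(out), "already")

  # tilt 52: rescale factor 1/sin(52 deg) = 1.2690
  st52 <- image_stack(array(runif(100 * 30 * 2, 0, 255), c(100, 30, 2)),
                      pixel_size_nm = 10, slice_thickness_nm = 30,
                      tilt_deg = 52, aligned = TRUE)
  out52 <- correct_foreshortening(st52)
  expect_equal(dim(out52$intensities)[1], round(100 * 1.2690))

  bad <- st52
  bad$tilt_deg <- 0
  expect_error(correct_foreshortening(bad), "tilt")
})

test_that("acquire-then-correct restores a calibration bar within 1 px", {
  # a 600 nm bar of pillar material on substrate, no cell
  lab <- array(0L, c(80, 40, 6))
  lab[1:4, , ] <- 1L
  lab[5:44, 15:25, ] <- 2L  # bar: 40 rows tall
  vol <- label_volume(lab, c(15, 15, 30))
  acq <- acquisition_params(tilt_deg = 52, slice_thickness_nm = 30,
                            pixel_size_nm = 15)
  sim <- simulate_acquisition(vol, acq, seed = 1)
  st <- correct_foreshortening(sim$stack)
  st$aligned <- TRUE
  seg <- segment_labels(st)
  bar_rows <- range(which(apply(seg$labels == 2L, 1, any)))
  expect_lte(abs(diff(bar_rows) + 1 - 40), 1)
})

test_that("segmentation recovers labels from clean and noisy stacks", {
  # noiseless: exact voxelwise agreement after the identity geometry path
  sc <- phantom_scene(preset = "ah-ns-medium", cell_kind = "coccus",
                      interactions = c("penetration", "none"), seed = 7,
                      measure_realized = FALSE)
  acq <- acquisition_params(tilt_deg = 90, slice_thickness_nm = 20,
                            pixel_size_nm = 15)
  sim <- simulate_acquisition(sc$volume, acq, seed = 1)
  st <- sim$stack
  st$aligned <- TRUE
  st <- correct_foreshortening(st)
  seg <- segment_labels(st)
  expect_identical(seg$labels, sc$volume$labels)
  expect_equal(seg$spacing_nm, sc$volume$spacing_nm)

  # full corruption: at least 99% voxelwise agreement
  ch <- phantom_chain()
  truth <- ch$scene$volume$labels
  got <- ch$seg$labels
  ny <- min(dim(truth)[1], dim(got)[1])
  nx <- min(dim(truth)[2], dim(got)[2])
  agree <- mean(got[1:ny, 1:nx, ] == truth[1:ny, 1:nx, ])
  expect_gte(agree, 0.99)
})

test_that("degenerate stacks segment to background or fail informatively", {
  flat <- image_stack(array(10, c(20, 20, 3)), pixel_size_nm = 10,
                      slice_thickness_nm = 30, aligned = TRUE,
                      foreshortening_corrected = TRUE)
  seg <- segment_labels(flat)
  expect_true(all(seg$labels == 0L))
  expect_error(segment_labels(flat, thresholds = "auto"),
               "thresholding failure")
  unc <- image_stack(array(10, c(20, 20, 3)), pixel_size_nm = 10,
                     slice_thickness_nm = 30)
  expect_error(segment_labels(unc), "aligned")
})

test_that("multi-level Otsu finds the synthetic class structure", {
  set.seed(11)
  levels <- c(20, 60, 90, 160, 200)
  img <- array(rnorm(8000, sample(levels, 8000, replace = TRUE,
                                  prob = c(0.5, 0.15, 0.15, 0.1, 0.1)), 4),
               c(20, 20, 20))
  st <- image_stack(pmin(pmax(img, 0), 255), pixel_size_nm = 10,
                    slice_thickness_nm = 30, aligned = TRUE,
                    foreshortening_corrected = TRUE)
  seg <- segment_labels(st, thresholds = "auto", n_classes = 5,
                        min_component_voxels = 1)
  # auto cuts must separate the five populations like the fixed cuts do
  ref <- segment_labels(st, min_component_voxels = 1)
  expect_gte(mean(seg$labels == ref$labels), 0.99)
})

test_that("stack TIFF round-trips losslessly with metadata", {
  arr <- array(as.numeric(sample(0:255, 30 * 20 * 4, replace = TRUE)),
               c(30, 20, 4))
  st <- image_stack(arr, pixel_size_nm = 12, slice_thickness_nm = 20,
                    tilt_deg = 52)
  path <- tempfile(fileext = ".tif")
  write_stack(st, path)
  rt <- read_stack(path)
  expect_identical(rt$intensities, arr)
  expect_equal(rt$pixel_size_nm, 12)
  expect_equal(rt$slice_thickness_nm, 20)

  # single-page stacks read back with one slice
  one <- image_stack(arr[, , 1, drop = FALSE], pixel_size_nm = 12,
                     slice_thickness_nm = 20)
  p1 <- tempfile(fileext = ".tif")
  write_stack(one, p1)
  expect_equal(dim(read_stack(p1)$intensities)[3], 1)

  # missing sidecar: defaults applied with a warning
  file.remove(paste0(path, ".json"))
  expect_warning(rt2 <- read_stack(path), "sidecar")
  expect_equal(rt2$pixel_size_nm, 10)
  expect_error(read_stack(tempfile()), "no such file")
})

test_that("label volumes round-trip through 16-bit TIFF", {
  sc <- phantom_scene(preset = "ah-ns-medium", cell_kind = "coccus",
                      interactions = "none", seed = 2,
                      measure_realized = FALSE)
  path <- tempfile(fileext = ".tif")
  write_label_volume(sc$volume, path)
  rt <- read_label_volume(path)
  expect_identical(rt$labels, sc$volume$labels)
  expect_equal(rt$spacing_nm, sc$volume$spacing_nm)
})
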