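test_that("surface area matches closed forms on analytic meshes", {
  # explicit 12-triangle cube, 1000 nm side: exactly 6 um2
  expect_equal(surface_area(cube_mesh(1000)), 6.0, tolerance = 1e-12)

  # refined icospheres approach 4 pi r^2 = 4 um2 at r = 564.19 nm from below
  r <- sqrt(4 / (4 * pi)) * 1000
  errs <- vapply(1:3, function(s)
    abs(surface_area(icosphere_mesh(r, s)) - 4.0), numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)

  # empty mesh: zero area
  empty <- tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  expect_equal(surface_area(empty), 0)

  bad <- cube_mesh(1000)
  bad$vertices[1, 1] <- NaN
  expect_error(surface_area(bad), "non-finite")
})

test_that("enclosed volume integrates the divergence theorem correctly", {
  expect_equal(enclosed_volume(cube_mesh(1000)), 1.0, tolerance = 1e-12)

  # inward-oriented cube: same magnitude, orientation warning
  inv <- cube_mesh(1000)
  inv$faces <- inv$faces[, c(1, 3, 2)]
  expect_warning(v <- enclosed_volume(inv), "inward")
  expect_equal(v, 1.0, tolerance = 1e-12)

  # icosphere r = 500 nm converges to 0.5236 um3
  expect_equal(enclosed_volume(icosphere_mesh(500, 4)), 0.5236,
               tolerance = 0.005)

  open_mesh <- cube_mesh(1000)
  open_mesh$faces <- open_mesh$faces[-1, , drop = FALSE]
  expect_error(enclosed_volume(open_mesh), "3 open edges")
})

test_that("interior depth field measures distance into the cell", {
  sph <- digital_sphere_volume(300, 10)
  d <- interior_depth_field(sph)
  ctr <- (dim(sph$labels) + 1) / 2
  expect_equal(d[ctr[1], ctr[2], ctr[3]], 300, tolerance = 10 / 300 * 300)
  expect_lte(abs(d[ctr[1], ctr[2], ctr[3]] - 300), 10)

  # voxels just inside the surface are at most one diagonal deep
  shallow <- d[d > 0]
  expect_lte(min(shallow), sqrt(3) * 10)

  # solid slab 100 nm thick: max depth at the midplane is ~50 nm
  lab <- array(0L, c(40, 40, 40))
  lab[16:25, , ] <- 4L
  slab <- label_volume(lab, c(10, 10, 10))
  expect_lte(abs(max(interior_depth_field(slab, close_radius_nm = 0)) - 50), 10)

  expect_error(interior_depth_field(
    label_volume(array(0L, c(4, 4, 4)), c(10, 10, 10))), "empty")
})

test_that("penetration depth is the apex depth and zero off-contact", {
  ch <- phantom_chain()
  gi <- ch$sim$ground_truth$interactions
  pen <- gi[gi$intended_class == "penetration", ]
  rec <- ch$cmp$contacts[ch$cmp$contacts$intended_class == "penetration", ]
  tol <- max(ch$scene$volume$spacing_nm)
  expect_lte(abs(rec$measured_depth_nm - pen$intended_depth_nm), tol)

  # a pillar nowhere near the cell has depth 0 (no channel to seal here,
  # so measure without closing to keep the surface exactly at the mask)
  sph <- digital_sphere_volume(300, 10)
  d <- interior_depth_field(sph, close_radius_nm = 0)
  far <- array(FALSE, dim(sph$labels))
  far[1:3, 1:3, 1:3] <- TRUE
  expect_equal(penetration_depth(far, d), 0)
  expect_error(penetration_depth(array(FALSE, dim(d)), d), "empty")

  # a pillar poked 100 nm into an analytic digital sphere reads ~100 nm
  lab <- sph$labels
  ctr <- (dim(lab) + 1) / 2
  probe <- array(FALSE, dim(lab))
  probe[(ctr[1] - 30):(ctr[1] - 30 + 10), ctr[2], ctr[3]] <- TRUE  # 100 nm in
  expect_lte(abs(penetration_depth(probe, d) - 100), sqrt(3) * 10)
})

test_that("tip contact area matches the disc closed form and is monotone", {
  # flat envelope over a flat-topped cylinder, tip radius 25 nm, gap g,
  # epsilon e: the faces within e of the pillar cover the disc plus the rim
  # annulus reachable past the edge, a disc of radius 25 + sqrt(e^2 - g^2)
  cyl <- capped_cylinder_mesh(25, 300)
  patch <- plane_patch_mesh(400, y_nm = 303, n = 160)
  ca <- tip_contact_area(patch, cyl, epsilon_nm = 5)
  expect_equal(ca$tip_contact_area_nm2, pi * (25 + sqrt(5^2 - 3^2))^2,
               tolerance = 0.10)
  expect_identical(ca$contact_zone, "tip")
  # at a gap close to epsilon the rim reach vanishes and the contact is the
  # disc area itself
  near <- tip_contact_area(plane_patch_mesh(400, y_nm = 304.9, n = 160),
                           cyl, epsilon_nm = 5)
  expect_equal(near$tip_contact_area_nm2, pi * 25^2, tolerance = 0.10)

  # far-away pillar: zero contact
  far <- tip_contact_area(plane_patch_mesh(400, y_nm = 500), cyl,
                          epsilon_nm = 20)
  expect_equal(far$tip_contact_area_nm2, 0)

  # monotone non-decreasing in epsilon
  areas <- vapply(c(3, 5, 10, 25), function(e)
    tip_contact_area(patch, cyl, epsilon_nm = e)$tip_contact_area_nm2,
    numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("per-pillar contact areas add up to the report total", {
  ch <- phantom_chain()
  rec <- ch$res$records
  rep <- ch$res$reports[[1]]
  expect_equal(rep$total_tip_contact_area_nm2, sum(rec$tip_contact_area_nm2))
  expect_equal(rep$contact_surface_area_pct,
               100 * sum(rec$tip_contact_area_nm2) /
                 (rep$envelope_surface_area_um2 * 1e6))
})

test_that("deformation depth recovers dimples and ignores outward bulges", {
  ref <- icosphere_mesh(500, 3)
  expect_equal(deformation_depth(ref, ref, c(0, -500, 0)), 0)

  # an inward dimple of 60 nm at the south pole
  dimpled <- ref
  v <- dimpled$vertices
  s <- sqrt(v[, 1]^2 + v[, 3]^2)
  south <- v[, 2] < 0
  dent <- ifelse(south & s < 150, 60 * 0.5 * (1 + cos(pi * s / 150)), 0)
  nrm <- v / sqrt(rowSums(v^2))
  dimpled$vertices <- v - nrm * dent
  d <- deformation_depth(dimpled, ref, c(0, -500, 0), radius_nm = 150,
                         quantile = 1)
  expect_equal(d, 60, tolerance = 0.05)

  # an outward bulge reads zero
  bulged <- ref
  bulged$vertices <- v + nrm * dent
  expect_equal(deformation_depth(bulged, ref, c(0, -500, 0)), 0)
})

test_that("phantom dimples are recovered through the full pipeline", {
  ch <- phantom_chain()
  cmpc <- ch$cmp$contacts
  def <- cmpc[cmpc$intended_class == "deformation", ]
  tol <- max(ch$scene$volume$spacing_nm)
  expect_identical(def$assigned_class, "deformation")
  expect_lte(abs(def$measured_depth_nm - def$realized_deformation_depth_nm),
             tol)
})

test_that("field characterization returns exact moments and recovers presets", {
  df <- data.frame(pillar_id = 1:4, base_x_nm = c(100, 300, 600, 900),
                   base_z_nm = c(100, 400, 700, 900),
                   axis_x = 0, axis_y = 1, axis_z = 0,
                   height_nm = c(100, 200, 300, 400),
                   tip_diameter_nm = c(40, 50, 60, 70),
                   base_diameter_nm = c(80, 100, 120, 140))
  ch <- characterize_field(df, field_area_um2 = 1)
  expect_equal(ch$density_per_um2, 4)
  expect_equal(ch$height_mean_nm, 250)
  expect_equal(ch$tip_diameter_mean_nm, 55)

  expect_error(characterize_field(df), "field_area_um2")
  empty <- characterize_field(df[0, ], field_area_um2 = 1)
  expect_equal(empty$density_per_um2, 0)
  expect_true(is.na(empty$height_mean_nm))

  # voxel route on a separable field (hard-core spacing above the base
  # diameter, so no two pillars fuse into one 26-connected component)
  p <- pillar_field_params(density_per_um2 = 6, height_mean_nm = 400,
                           height_sd_nm = 50, tip_diameter_mean_nm = 60,
                           tip_diameter_sd_nm = 6,
                           orientation_mode = "aligned",
                           field_size_um = c(2, 2), min_spacing_nm = 300)
  f <- sample_pillar_field(p, seed = 31)
  sc <- compose_scene(list(), f, list(), spacing_nm = c(10, 10, 10),
                      scene_size_nm = c(700, 2000, 2000),
                      measure_realized = FALSE)
  chv <- characterize_field(sc$volume)
  expect_equal(chv$n_pillars, nrow(f))
  expect_equal(chv$density_per_um2, nrow(f) / 4, tolerance = 0.01)
  # height from voxels: mean within quantization + sampling slack
  expect_lt(abs(chv$height_mean_nm - mean(f$height_nm)), 40)
})
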