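geom_stub <- function(pen = 0, def = 0, area = 1000, zone = "tip",
                      hf = 0.1, id = 1L) {
  structure(list(pillar_id = id, tip_contact_area_nm2 = area,
                 contact_zone = zone, contact_height_fraction = hf,
                 penetration_depth_nm = pen, deformation_depth_nm = def,
                 contact_centroid_nm = c(0, 0, 0), epsilon_nm = 30),
            class = "contact_geometry")
}

test_that("the decision ladder assigns classes in order of precedence", {
  th <- classification_thresholds()

  # a 74.7 nm penetration with no turgor loss is penetration, not rupture
  expect_identical(classify_contact(geom_stub(pen = 74.7), 0, th)$interaction_class,
                   "penetration")
  # penetration plus a volume deficit at/above threshold is rupture
  expect_identical(classify_contact(geom_stub(pen = 29.5), 0.35, th)$interaction_class,
                   "rupture")
  # deformation at/above tau
  expect_identical(classify_contact(geom_stub(def = 38), 0, th)$interaction_class,
                   "deformation")
  # mid-height sidewall contact with no depths: impedance (lateral pinning)
  expect_identical(classify_contact(geom_stub(zone = "sidewall", hf = 0.5), 0,
                                    th)$interaction_class,
                   "impedance")
  # low sidewall or tip contact without depths: no effect
  expect_identical(classify_contact(geom_stub(zone = "sidewall", hf = 0.1), 0,
                                    th)$interaction_class, "none")
  expect_identical(classify_contact(geom_stub(), 0, th)$interaction_class,
                   "none")
  # no contact: no record
  expect_null(classify_contact(geom_stub(area = 0), 0, th))
})

test_that("inconsistent geometries raise data-integrity errors", {
  th <- classification_thresholds()
  expect_error(classify_contact(geom_stub(pen = 50, area = 0), 0, th),
               "inconsistent")
  expect_error(classify_contact(geom_stub(def = 40, area = 0), 0, th),
               "inconsistent")
  expect_error(classify_contact(geom_stub(pen = 50, def = 30), 0, th),
               "mutually exclusive")
  expect_error(classification_thresholds(tau_deform_nm = 0))
  expect_error(classification_thresholds(tau_rupture_volume_fraction = 1))
})

test_that("volume deficit is the clamped relative loss", {
  expect_equal(assess_volume_deficit(0.7, 1.0), 0.30)
  expect_equal(assess_volume_deficit(1.0, 1.0), 0)
  expect_equal(assess_volume_deficit(1.2, 1.0), 0)
  expect_error(assess_volume_deficit(0.5, 0), "positive")
})

test_that("every randomized geometry gets exactly one valid class", {
  th <- classification_thresholds()
  set.seed(99)
  for (i in 1:300) {
    area <- sample(c(0, runif(1, 10, 5e4)), 1, prob = c(0.15, 0.85))
    pen <- if (area > 0) sample(c(0, runif(1, 1, 120)), 1) else 0
    def <- if (pen > 0 || area == 0) 0 else sample(c(0, runif(1, 1, 120)), 1)
    g <- geom_stub(pen = pen, def = def, area = area,
                   zone = sample(c("tip", "sidewall"), 1),
                   hf = runif(1))
    rec <- classify_contact(g, runif(1, 0, 0.5), th)
    if (area == 0) {
      expect_null(rec)
      next
    }
    expect_s3_class(rec, "contact_record")
    cls <- rec$interaction_class
    expect_true(cls %in% c("none", "deformation", "penetration",
                           "rupture", "impedance"))
    # ContactRecord invariants
    if (cls %in% c("penetration", "rupture"))
      expect_gt(rec$penetration_depth_nm, 0)
    if (cls == "deformation")
      expect_gte(rec$deformation_depth_nm, th$tau_deform_nm)
    if (cls == "none") {
      expect_equal(rec$penetration_depth_nm, 0)
      expect_lt(rec$deformation_depth_nm, th$tau_deform_nm)
    }
  }
})

test_that("intended and assigned classes agree on a corrupted phantom", {
  ch <- phantom_chain()
  cmpc <- ch$cmp$contacts
  expect_identical(cmpc$assigned_class, cmpc$realized_class)
})
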