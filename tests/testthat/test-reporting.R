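record_stub <- function(cls, pen = 0, def = 0, area = 100) {
  data.frame(pillar_id = seq_along(cls), interaction_class = cls,
             penetration_depth_nm = pen, deformation_depth_nm = def,
             tip_contact_area_nm2 = area, stringsAsFactors = FALSE)
}

test_that("table-style formatting truncates percentages and marks averages", {
  # 3 contacts, 2 penetrating at 30.8 / 37.1 nm: 66.66 (truncated from 2/3)
  # and mean depth 33.95 with the averaged-values marker
  rec <- record_stub(c("penetration", "penetration", "none"),
                     pen = c(30.8, 37.1, 0))
  rep <- build_cell_report("S. aureus 1", 1.5, 0.14, rec)
  f <- format_cell_report(rep)
  expect_identical(unname(f["pct_penetrating"]), "66.66")
  expect_identical(unname(f["mean_penetration_depth_nm"]), "33.95*")
  expect_equal(rep$pct_penetrating, 200 / 3)
  expect_equal(rep$mean_penetration_depth_nm, 33.95)

  # single penetration renders without the marker
  rec1 <- record_stub(c("penetration", "none", "none"), pen = c(74.7, 0, 0))
  f1 <- format_cell_report(build_cell_report("c", 2.1, 0.28, rec1))
  expect_identical(unname(f1["mean_penetration_depth_nm"]), "74.70")

  # prose-style integer share rounds: 22 of 24 not penetrating -> 92%
  rec24 <- record_stub(c(rep("penetration", 2), rep("none", 22)))
  rep24 <- build_cell_report("e", 2.3, 0.23, rec24)
  expect_equal(round(100 * (rep24$total_contacts - rep24$n_penetrating) /
                       rep24$total_contacts), 92)
  expect_identical(unname(format_cell_report(rep24)["pct_penetrating"]),
                   "8.33")
})

test_that("empty reports are valid with null percentages", {
  rep <- build_cell_report("lone", 2.0, 0.3, NULL)
  expect_equal(rep$total_contacts, 0)
  expect_true(is.na(rep$pct_penetrating))
  expect_true(is.na(rep$mean_penetration_depth_nm))
  f <- format_cell_report(rep)
  expect_identical(unname(f["mean_penetration_depth_nm"]), "-")
})

test_that("count conservation and percentage identities hold on random reports", {
  set.seed(7)
  classes <- c("none", "deformation", "penetration", "rupture", "impedance")
  for (i in 1:50) {
    n <- sample(0:30, 1)
    cls <- sample(classes, n, replace = TRUE)
    rec <- if (n > 0)
      record_stub(cls, pen = ifelse(cls %in% c("penetration", "rupture"),
                                    runif(n, 20, 80), 0),
                  def = ifelse(cls == "deformation", runif(n, 15, 100), 0),
                  area = runif(n, 50, 5000))
    else NULL
    sa <- runif(1, 1, 15)
    rep <- build_cell_report(i, sa, runif(1, 0.1, 3), rec)
    expect_equal(rep$n_penetrating + rep$n_deforming + rep$n_impeding +
                   rep$n_none, rep$total_contacts)
    if (n > 0) {
      expect_equal(rep$pct_penetrating, 100 * rep$n_penetrating / n)
      expect_equal(rep$pct_deforming, 100 * rep$n_deforming / n)
      expect_equal(rep$pct_impeding, 100 * rep$n_impeding / n)
      expect_identical(rep$contact_surface_area_pct,
                       100 * rep$total_tip_contact_area_nm2 / (sa * 1e6))
      if (rep$n_penetrating > 0)
        expect_equal(rep$mean_penetration_depth_nm,
                     mean(rec$penetration_depth_nm[
                       rec$interaction_class %in% c("penetration", "rupture")]))
    } else {
      expect_true(is.na(rep$pct_penetrating))
    }
  }
})

test_that("reports export to CSV with the fixed column order", {
  reps <- list(build_cell_report("a", 1.5, 0.14,
                                 record_stub(c("penetration", "none"),
                                             pen = c(30, 0))),
               build_cell_report("b", 2.3, 0.31, NULL))
  path <- tempfile(fileext = ".csv")
  export_reports(reps, path, "csv")
  df <- read.csv(path)
  expect_equal(nrow(df), 2)
  expect_identical(names(df)[1:3],
                   c("cell_id", "envelope_surface_area_um2", "cell_volume_um3"))
  expect_equal(df$total_contacts, c(2, 0))

  # empty list: header-only CSV
  p2 <- tempfile(fileext = ".csv")
  export_reports(list(), p2, "csv")
  expect_equal(nrow(read.csv(p2)), 0)
})

test_that("reports round-trip through JSON", {
  rep <- build_cell_report("cell-1", 2.3, 0.23,
                           record_stub(c("penetration", "deformation", "none"),
                                       pen = c(29.51, 0, 0),
                                       def = c(0, 51, 0)))
  path <- tempfile(fileext = ".json")
  export_reports(list(rep), path, "json")
  back <- read_reports(path)[[1]]
  for (f in c("envelope_surface_area_um2", "cell_volume_um3", "n_penetrating",
              "pct_penetrating", "mean_penetration_depth_nm", "total_contacts",
              "total_tip_contact_area_nm2", "contact_surface_area_pct"))
    expect_equal(back[[f]], rep[[f]], tolerance = 1e-12)
  expect_equal(back$records$interaction_class, rep$records$interaction_class)
})
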