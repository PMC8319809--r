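#' Idealized bacterial cell shape
#'
#' A coccus is a sphere of diameter `width_nm` (e.g. S. aureus, ~1 um); a rod
#' is a spherocylinder: a cylinder of length `length_nm - width_nm` capped by
#' hemispheres (e.g. E. coli, width ~500 nm). Analytic surface area and
#' volume are attached for oracle use.
#'
#' @param kind `"rod"` or `"coccus"`.
#' @param width_nm cell diameter (rod width or coccus diameter), nm.
#' @param length_nm rod total tip-to-tip length, nm (rods only; must be
#'   at least `width_nm`).
#' @param center_nm cell center, `c(x, y, z)` nm.
#' @param long_axis unit 3-vector, rod long axis (rods only).
#' @return an object of class `cell_shape` with `surface_area_um2` and
#'   `volume_um3` fields.
#' @export
cell_shape <- function(kind = c("coccus", "rod"), width_nm,
                       length_nm = NULL, center_nm = c(0, 0, 0),
                       long_axis = c(0, 0, 1)) {
  kind <- match.arg(kind)
  stopifnot(width_nm > 0, length(center_nm) == 3)
  r <- width_nm / 2
  if (kind == "coccus") {
    length_nm <- width_nm
    long_axis <- c(0, 0, 1)
    sa <- 4 * pi * r^2
    vol <- 4 / 3 * pi * r^3
  } else {
    if (is.null(length_nm))
      stop("rod cells need length_nm")
    if (length_nm < width_nm)
      stop("invalid rod dimensions: length_nm (", length_nm,
           ") must be >= width_nm (", width_nm, ")")
    long_axis <- long_axis / sqrt(sum(long_axis^2))
    cyl <- length_nm - width_nm
    sa <- 2 * pi * r * cyl + 4 * pi * r^2
    vol <- pi * r^2 * cyl + 4 / 3 * pi * r^3
  }
  structure(list(kind = kind, width_nm = width_nm, length_nm = length_nm,
                 center_nm = as.numeric(center_nm),
                 long_axis = as.numeric(long_axis),
                 surface_area_um2 = sa / 1e6,
                 volume_um3 = vol / 1e9),
            class = "cell_shape")
}

#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf("<cell_shape> %s, width %.4g nm, length %.4g nm, SA %.4g um2, V %.4g um3\n",
              x$kind, x$width_nm, x$length_nm, x$surface_area_um2, x$volume_um3))
  invisible(x)
}

# Segment endpoints of the spherocylinder skeleton (both equal the center
# for a coccus).
cell_segment <- function(cell) {
  hl <- (cell$length_nm - cell$width_nm) / 2
  a <- cell$center_nm - hl * cell$long_axis
  b <- cell$center_nm + hl * cell$long_axis
  list(a = a, b = b, r = cell$width_nm / 2)
}

# Distance from points (n x 3) to the cell skeleton segment; the cell
# surface is the set where this equals the cell radius.
dist_to_segment <- function(p, seg) {
  ab <- seg$b - seg$a
  ab2 <- sum(ab^2)
  if (ab2 == 0) {
    sqrt((p[, 1] - seg$a[1])^2 + (p[, 2] - seg$a[2])^2 + (p[, 3] - seg$a[3])^2)
  } else {
    t <- ((p[, 1] - seg$a[1]) * ab[1] + (p[, 2] - seg$a[2]) * ab[2] +
            (p[, 3] - seg$a[3]) * ab[3]) / ab2
    t <- pmin(pmax(t, 0), 1)
    qx <- seg$a[1] + t * ab[1]
    qy <- seg$a[2] + t * ab[2]
    qz <- seg$a[3] + t * ab[3]
    sqrt((p[, 1] - qx)^2 + (p[, 2] - qy)^2 + (p[, 3] - qz)^2)
  }
}

# Isotropically shrink a cell about its center to (1 - deficit) times its
# volume; models turgor-pressure loss after envelope rupture.
shrink_cell <- function(cell, volume_deficit_fraction) {
  stopifnot(volume_deficit_fraction >= 0, volume_deficit_fraction < 1)
  if (volume_deficit_fraction == 0) return(cell)
  s <- (1 - volume_deficit_fraction)^(1 / 3)
  cell_shape(kind = cell$kind,
             width_nm = cell$width_nm * s,
             length_nm = if (cell$kind == "rod") cell$length_nm * s else NULL,
             center_nm = cell$center_nm,
             long_axis = cell$long_axis)
}
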