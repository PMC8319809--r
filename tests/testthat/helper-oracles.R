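# Closed-form oracle constructions: analytic meshes and digital solids used
# to check the mesh/morphometry operations against textbook formulas.

# axis-aligned cube as 12 outward-oriented triangles
cube_mesh <- function(side_nm, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  v <- sweep(v * side_nm, 2, origin, `+`)
  # corner indices follow expand.grid order: x fastest
  quads <- rbind(c(1, 2, 4, 3),  # z = 0, normal -z
                 c(5, 7, 8, 6),  # z = 1, normal +z
                 c(1, 5, 6, 2),  # y = 0, normal -y
                 c(3, 4, 8, 7),  # y = 1, normal +y
                 c(1, 3, 7, 5),  # x = 0, normal -x
                 c(2, 6, 8, 4))  # x = 1, normal +x
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  m <- tri_mesh(v, f)
  orient_outward(m)
}

# subdivided icosahedron projected to a sphere of radius r
icosphere_mesh <- function(r_nm, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    nv <- nrow(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    f <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      rbind(c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }))
  }
  v <- v / sqrt(rowSums(v^2)) * r_nm
  orient_outward(tri_mesh(v, f))
}

# flip face winding if the signed volume comes out negative
orient_outward <- function(mesh) {
  if (signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  d <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) +
        a[, 2] * (b[, 3] * d[, 1] - b[, 1] * d[, 3]) +
        a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

# open cylinder (side wall + top disc fan), apex cap flat: a flat-topped
# pillar stand-in for the disc contact oracle
capped_cylinder_mesh <- function(radius_nm, height_nm, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring0 <- cbind(radius_nm * cos(th), 0, radius_nm * sin(th))
  ring1 <- cbind(radius_nm * cos(th), height_nm, radius_nm * sin(th))
  v <- rbind(ring0, ring1, c(0, height_nm, 0), c(0, 0, 0))
  top <- 2 * n + 1; bot <- 2 * n + 2
  f <- NULL
  for (i in seq_len(n)) {
    j <- i %% n + 1
    f <- rbind(f,
               c(i, n + i, n + j), c(i, n + j, j),   # wall
               c(n + i, top, n + j),                 # top fan
               c(j, bot, i))                         # bottom fan
  }
  orient_outward(tri_mesh(v, f))
}

# rectangular plane patch (in the xz plane at height y), triangulated grid
plane_patch_mesh <- function(extent_nm, y_nm, n = 24) {
  xs <- seq(-extent_nm / 2, extent_nm / 2, length.out = n + 1)
  g <- as.matrix(expand.grid(x = xs, z = xs))
  v <- cbind(g[, 1], y_nm, g[, 2])
  idx <- function(i, j) (j - 1) * (n + 1) + i
  f <- NULL
  for (j in seq_len(n)) for (i in seq_len(n))
    f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  tri_mesh(v, f)
}

# digital solid sphere as a label volume (cytosol label), isotropic spacing
digital_sphere_volume <- function(r_nm, spacing_nm, label = 4L, pad = 3) {
  n <- 2 * ceiling(r_nm / spacing_nm) + 2 * pad + 1
  c0 <- (n - 1) / 2
  ix <- 0:(n - 1)
  g <- expand.grid(y = ix, x = ix, z = ix)
  inside <- ((g$y - c0)^2 + (g$x - c0)^2 + (g$z - c0)^2) * spacing_nm^2 <= r_nm^2
  label_volume(array(ifelse(inside, label, 0L), c(n, n, n)),
               rep(spacing_nm, 3))
}

digital_cube_volume <- function(side_vox, spacing_nm, label = 4L, pad = 5) {
  n <- side_vox + 2 * pad
  lab <- array(0L, c(n, n, n))
  sel <- (pad + 1):(pad + side_vox)
  lab[sel, sel, sel] <- label
  label_volume(lab, rep(spacing_nm, 3))
}

digital_spherocylinder_volume <- function(r_nm, length_nm, spacing_nm,
                                          label = 4L, pad = 3) {
  nxy <- 2 * ceiling(r_nm / spacing_nm) + 2 * pad + 1
  nz <- ceiling(length_nm / spacing_nm) + 2 * pad + 1
  cxy <- (nxy - 1) / 2; cz <- (nz - 1) / 2
  g <- expand.grid(y = 0:(nxy - 1), x = 0:(nxy - 1), z = 0:(nz - 1))
  half <- (length_nm - 2 * r_nm) / 2 / spacing_nm
  dz <- pmax(abs(g$z - cz) - half, 0)
  inside <- ((g$y - cxy)^2 + (g$x - cxy)^2 + dz^2) * spacing_nm^2 <= r_nm^2
  label_volume(array(ifelse(inside, label, 0L), c(nxy, nxy, nz)),
               rep(spacing_nm, 3))
}
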