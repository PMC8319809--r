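#' Imposed pillar-cell interaction
#'
#' Declares what a given pillar does to the cell it meets: `none` (apex
#' touches the envelope with no morphological change), `deformation` (a
#' smooth inward dimple of the given depth and radius, no breach),
#' `penetration` (the apex ends `depth_nm` past the envelope outer surface,
#' inside the cell), `rupture` (penetration plus isotropic cell shrinkage to
#' `1 - volume_deficit_fraction` of the reference volume), or `impedance`
#' (the pillar flank tangent to the cell flank, zero indentation).
#'
#' @param pillar_id id of the pillar in the pillar spec table.
#' @param class interaction class.
#' @param depth_nm intended penetration or deformation depth (nm); must be 0
#'   for `none` and `impedance`, positive otherwise.
#' @param dimple_radius_nm lateral radius of the deformation dimple (nm).
#' @param volume_deficit_fraction cell volume fraction lost to rupture,
#'   in \[0, 1).
#' @return an object of class `interaction_spec`.
#' @export
interaction_spec <- function(pillar_id,
                             class = c("none", "deformation", "penetration",
                                       "rupture", "impedance"),
                             depth_nm = 0, dimple_radius_nm = 150,
                             volume_deficit_fraction = 0) {
  class <- match.arg(class)
  if (class %in% c("none", "impedance")) {
    if (depth_nm != 0)
      stop("depth_nm must be 0 for class ", class)
  } else {
    if (depth_nm <= 0)
      stop("depth_nm must be positive for class ", class)
  }
  if (class == "rupture" && volume_deficit_fraction <= 0)
    stop("rupture needs a positive volume_deficit_fraction")
  stopifnot(dimple_radius_nm > 0,
            volume_deficit_fraction >= 0, volume_deficit_fraction < 1)
  structure(list(pillar_id = as.integer(pillar_id), class = class,
                 depth_nm = depth_nm, dimple_radius_nm = dimple_radius_nm,
                 volume_deficit_fraction = volume_deficit_fraction),
            class = "interaction_spec")
}

# --- pillar geometry -------------------------------------------------------

# rows of the pillar spec data.frame -> list geometry
pillar_geom <- function(row, substrate_top_nm) {
  u <- c(row$axis_x, row$axis_y, row$axis_z)
  u <- u / sqrt(sum(u^2))
  rt <- row$tip_diameter_nm / 2
  rb <- row$base_diameter_nm / 2
  h <- row$height_nm
  list(B = c(row$base_x_nm, substrate_top_nm, row$base_z_nm),
       u = u, h = h, hc = max(h - rt, 0), rt = rt, rb = rb)
}

pillar_apex <- function(g) g$B + g$u * g$h

# Vectorized inside test for points p (n x 3), with a small extension below
# the base so the pillar fuses with the substrate.
pillar_inside <- function(p, g, base_slack_nm = 0) {
  qx <- p[, 1] - g$B[1]; qy <- p[, 2] - g$B[2]; qz <- p[, 3] - g$B[3]
  t <- qx * g$u[1] + qy * g$u[2] + qz * g$u[3]
  rho2 <- pmax(qx^2 + qy^2 + qz^2 - t^2, 0)
  rcone <- g$rb + (g$rt - g$rb) * pmin(pmax(t, 0), g$hc) / max(g$hc, 1e-9)
  in_cone <- t >= -base_slack_nm & t <= g$hc & rho2 <= rcone^2
  C <- g$B + g$u * g$hc
  in_cap <- (p[, 1] - C[1])^2 + (p[, 2] - C[2])^2 + (p[, 3] - C[3])^2 <= g$rt^2
  in_cone | in_cap
}

# Approximate unsigned distance from points to the pillar surface (cone slant
# corrected, hemispherical cap exact); adequate for epsilon-shell membership.
pillar_surface_distance <- function(p, g) {
  qx <- p[, 1] - g$B[1]; qy <- p[, 2] - g$B[2]; qz <- p[, 3] - g$B[3]
  t <- qx * g$u[1] + qy * g$u[2] + qz * g$u[3]
  rho <- sqrt(pmax(qx^2 + qy^2 + qz^2 - t^2, 0))
  slant <- cos(atan2(g$rb - g$rt, max(g$hc, 1e-9)))
  rcone <- g$rb + (g$rt - g$rb) * pmin(pmax(t, 0), g$hc) / max(g$hc, 1e-9)
  d_cone <- abs(rho - rcone) * slant
  d_cone[t < 0 | t > g$hc] <- Inf
  C <- g$B + g$u * g$hc
  d_cap <- abs(sqrt((p[, 1] - C[1])^2 + (p[, 2] - C[2])^2 +
                      (p[, 3] - C[3])^2) - g$rt)
  d_cap[t <= g$hc] <- Inf
  out <- pmin(d_cone, d_cap)
  # below the base: distance to the base disc plane (coarse, rarely relevant)
  out[t < -1] <- Inf
  out
}

# First crossing t (axis length) where the pillar axis ray reaches
# skeleton-distance `target` from the cell, i.e. where the apex should sit
# to realize a given relationship to the envelope. NA when the ray misses.
axis_entry_t <- function(g, cell, target, t_max = 6000) {
  seg <- cell_segment(cell)
  f <- function(t) {
    p <- matrix(g$B + g$u * t, 1, 3)
    dist_to_segment(p, seg) - target
  }
  ts <- seq(0, t_max, by = 2)
  vals <- vapply(ts, f, numeric(1))
  below <- which(vals <= 0)
  if (length(below) == 0) return(NA_real_)
  k <- below[1]
  if (k == 1) return(ts[1])
  stats::uniroot(f, c(ts[k - 1], ts[k]), tol = 1e-3)$root
}

# --- scene composition -----------------------------------------------------

#' Compose a ground-truthed phantom scene
#'
#' Voxelizes substrate, nanopillars, envelope shell and cytosol onto a label
#' grid and imposes each requested interaction geometrically, adjusting the
#' referenced pillar so the intended contact relationship holds exactly:
#' penetrating pillars end `depth_nm` inside the cell (through a local
#' envelope opening), deforming pillars indent the envelope by a smooth
#' radial dimple they rest in, impeding pillars are shifted until their flank
#' is tangent to the cell flank, and rupture shrinks the cell isotropically
#' before placing the penetrating pillar. Ground truth (realized classes,
#' depths measured on the voxel grid, analytic cell morphometrics) is
#' recorded for every downstream check.
#'
#' @param cells list of [cell_shape()] (or a single one).
#' @param pillars pillar spec `data.frame` from [sample_pillar_field()].
#' @param interactions list of [interaction_spec()]; at most one per pillar.
#' @param spacing_nm voxel spacing `c(y, x, z)` nm (z = slice thickness).
#' @param scene_size_nm grid extent `c(y, x, z)` nm; derived from contents
#'   when `NULL`.
#' @param substrate_thickness_nm thickness of the substrate slab at the
#'   bottom of the grid.
#' @param shell_thickness_nm envelope shell thickness (a rendering construct;
#'   must exceed one voxel).
#' @param max_voxels resource guard on the grid size.
#' @param measure_realized also measure realized depths/areas on the pristine
#'   grid (meshes the scene once; slightly slower).
#' @return list with `volume` (a [label_volume()] with `pillar_ids`) and
#'   `ground_truth`.
#' @export
compose_scene <- function(cells, pillars, interactions = list(),
                          spacing_nm = c(15, 15, 20),
                          scene_size_nm = NULL,
                          substrate_thickness_nm = 60,
                          shell_thickness_nm = 40,
                          max_voxels = 2.5e7,
                          measure_realized = TRUE) {
  if (inherits(cells, "cell_shape")) cells <- list(cells)
  stopifnot(all(vapply(cells, inherits, TRUE, "cell_shape")),
            is.data.frame(pillars))
  if (inherits(interactions, "interaction_spec"))
    interactions <- list(interactions)
  if (any(shell_thickness_nm <= spacing_nm[1:2]))
    stop("shell_thickness_nm must exceed one voxel")
  ids <- vapply(interactions, function(i) i$pillar_id, integer(1))
  if (anyDuplicated(ids))
    stop("contradictory interactions: pillar(s) ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         " referenced more than once")
  if (length(ids) > 0 && !all(ids %in% pillars$pillar_id))
    stop("interaction references unknown pillar id(s): ",
         paste(setdiff(ids, pillars$pillar_id), collapse = ", "))

  sub_top <- substrate_thickness_nm

  # assign each interaction to the nearest cell, shrink ruptured cells first
  cell_of <- integer(length(interactions))
  for (k in seq_along(interactions)) {
    row <- pillars[pillars$pillar_id == interactions[[k]]$pillar_id, ]
    g <- pillar_geom(row, sub_top)
    d <- vapply(cells, function(cl)
      dist_to_segment(matrix(g$B, 1, 3), cell_segment(cl)), numeric(1))
    cell_of[k] <- which.min(d)
  }
  reference_cells <- cells
  for (k in seq_along(interactions)) {
    it <- interactions[[k]]
    if (it$class == "rupture")
      cells[[cell_of[k]]] <- shrink_cell(cells[[cell_of[k]]],
                                         it$volume_deficit_fraction)
  }

  # realize each interaction by adjusting the referenced pillar
  dimples <- list()  # per-cell list of dimple descriptors
  gt_int <- data.frame()
  for (k in seq_along(interactions)) {
    it <- interactions[[k]]
    ci <- cell_of[k]
    cell <- cells[[ci]]
    R <- cell$width_nm / 2
    if (it$depth_nm > R)
      stop("requested depth ", it$depth_nm, " nm exceeds cell radius ", R)
    ri <- which(pillars$pillar_id == it$pillar_id)
    g <- pillar_geom(pillars[ri, ], sub_top)

    if (it$class == "impedance") {
      # shift the base horizontally until the flank is tangent to the cell
      seg <- cell_segment(cell)
      w <- g$B - cell$center_nm
      w[2] <- 0
      if (sum(w^2) < 1e-6) w <- c(1, 0, 0)
      w <- w / sqrt(sum(w^2))
      # radius of the pillar at the closest-approach height (near cell center)
      t_at <- min(max((cell$center_nm[2] - sub_top) / g$u[2], 0), g$hc)
      r_at <- g$rb + (g$rt - g$rb) * t_at / max(g$hc, 1e-9)
      target <- R + r_at
      cur <- dist_to_segment(matrix(g$B + g$u * t_at, 1, 3), seg)
      shift <- (target - cur)
      pillars$base_x_nm[ri] <- pillars$base_x_nm[ri] + shift * w[1]
      pillars$base_z_nm[ri] <- pillars$base_z_nm[ri] + shift * w[3]
      g <- pillar_geom(pillars[ri, ], sub_top)
      if (pillar_apex(g)[2] < cell$center_nm[2])
        warning("impedance pillar ", it$pillar_id,
                " is shorter than the cell equator; contact will sit low")
      apex <- pillar_apex(g)
      entry <- apex  # tangent point (approximately)
    } else {
      target <- switch(it$class,
                       none = R,
                       deformation = R - it$depth_nm,
                       penetration = R - it$depth_nm,
                       rupture = R - it$depth_nm)
      t_apex <- axis_entry_t(g, cell, target)
      if (is.na(t_apex))
        stop("pillar ", it$pillar_id, " axis does not reach cell ", ci)
      if (it$class == "deformation") # rest the apex on the dimple floor
        t_apex <- t_apex - 0.75 * max(spacing_nm)
      pillars$height_nm[ri] <- t_apex
      g <- pillar_geom(pillars[ri, ], sub_top)
      apex <- pillar_apex(g)
      t_entry <- axis_entry_t(g, cell, R)
      entry <- g$B + g$u * t_entry
      if (it$class == "deformation") {
        seg <- cell_segment(cell)
        q <- closest_on_segment(apex, seg)
        nrm <- apex - q
        nrm <- nrm / sqrt(sum(nrm^2))
        dimples[[length(dimples) + 1]] <-
          list(cell = ci, apex = apex, normal = nrm,
               depth = it$depth_nm, radius = it$dimple_radius_nm)
      }
    }
    gt_int <- rbind(gt_int, data.frame(
      pillar_id = it$pillar_id, cell_id = ci,
      intended_class = it$class, intended_depth_nm = it$depth_nm,
      dimple_radius_nm = it$dimple_radius_nm,
      volume_deficit_fraction = it$volume_deficit_fraction,
      apex_x_nm = apex[1], apex_y_nm = apex[2], apex_z_nm = apex[3],
      entry_x_nm = entry[1], entry_y_nm = entry[2], entry_z_nm = entry[3]))
  }

  # grid extents
  if (is.null(scene_size_nm)) {
    xs <- c(pillars$base_x_nm, vapply(cells, function(c) c$center_nm[1], 1))
    zs <- c(pillars$base_z_nm, vapply(cells, function(c) c$center_nm[3], 1))
    tops <- c(sub_top + pillars$height_nm,
              vapply(cells, function(c) c$center_nm[2] + c$width_nm / 2, 1))
    margin <- 150
    scene_size_nm <- c(max(tops) + margin,
                       max(xs) + margin, max(zs) + margin)
  }
  dims <- pmax(ceiling(scene_size_nm / spacing_nm), 4)
  if (prod(dims) > max_voxels)
    stop("voxel budget exceeded: grid ", paste(dims, collapse = " x "),
         " = ", prod(dims), " > max_voxels = ", max_voxels)

  ys <- (seq_len(dims[1]) - 1) * spacing_nm[1]
  xs <- (seq_len(dims[2]) - 1) * spacing_nm[2]
  zs <- (seq_len(dims[3]) - 1) * spacing_nm[3]

  labels <- array(0L, dims)
  pillar_id_grid <- array(0L, dims)
  labels[ys <= sub_top, , ] <- NC_LABELS[["substrate"]]

  bbox_idx <- function(coords, lo, hi)
    which(coords >= lo & coords <= hi)

  # paint cells (envelope shell + cytosol), with their dimples
  cell_voxels <- integer(length(cells))
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    R <- cell$width_nm / 2
    seg <- cell_segment(cell)
    lo <- pmin(seg$a, seg$b) - R - 2 * max(spacing_nm)
    hi <- pmax(seg$a, seg$b) + R + 2 * max(spacing_nm)
    iy <- bbox_idx(ys, lo[2], hi[2]); ix <- bbox_idx(xs, lo[1], hi[1])
    iz <- bbox_idx(zs, lo[3], hi[3])
    if (!length(iy) || !length(ix) || !length(iz)) next
    ny <- length(iy); nx <- length(ix); nz <- length(iz)
    P <- cbind(rep(xs[ix], each = ny, times = nz),
               rep(ys[iy], times = nx * nz),
               rep(zs[iz], each = ny * nx))
    d <- dist_to_segment(P, seg)
    dent <- rep(0, nrow(P))
    for (dm in dimples) {
      if (dm$cell != ci) next
      rel <- cbind(P[, 1] - dm$apex[1], P[, 2] - dm$apex[2],
                   P[, 3] - dm$apex[3])
      along <- rel[, 1] * dm$normal[1] + rel[, 2] * dm$normal[2] +
        rel[, 3] * dm$normal[3]
      s <- sqrt(pmax(rowSums(rel^2) - along^2, 0))
      bump <- ifelse(s < dm$radius,
                     dm$depth * 0.5 * (1 + cos(pi * s / dm$radius)), 0)
      dent <- pmax(dent, bump)
    }
    interior <- d <= R - dent
    cyto <- d <= R - dent - shell_thickness_nm
    sub <- labels[iy, ix, iz]
    sub[array(interior, c(ny, nx, nz))] <- NC_LABELS[["envelope"]]
    sub[array(cyto, c(ny, nx, nz))] <- NC_LABELS[["cytosol"]]
    labels[iy, ix, iz] <- sub
    cell_voxels[ci] <- sum(interior)
  }

  # paint pillars last: they override the envelope locally (the "opening")
  for (ri in seq_len(nrow(pillars))) {
    g <- pillar_geom(pillars[ri, ], sub_top)
    apex <- pillar_apex(g)
    lo <- pmin(g$B, apex) - g$rb - 2 * max(spacing_nm)
    hi <- pmax(g$B, apex) + g$rb + 2 * max(spacing_nm)
    iy <- bbox_idx(ys, lo[2], hi[2]); ix <- bbox_idx(xs, lo[1], hi[1])
    iz <- bbox_idx(zs, lo[3], hi[3])
    if (!length(iy) || !length(ix) || !length(iz)) next
    ny <- length(iy); nx <- length(ix); nz <- length(iz)
    P <- cbind(rep(xs[ix], each = ny, times = nz),
               rep(ys[iy], times = nx * nz),
               rep(zs[iz], each = ny * nx))
    inside <- pillar_inside(P, g, base_slack_nm = 2 * spacing_nm[1])
    m <- array(inside, c(ny, nx, nz))
    sub <- labels[iy, ix, iz]
    sub[m] <- NC_LABELS[["pillar"]]
    labels[iy, ix, iz] <- sub
    idsub <- pillar_id_grid[iy, ix, iz]
    idsub[m] <- pillars$pillar_id[ri]
    pillar_id_grid[iy, ix, iz] <- idsub
    # tips narrower than a voxel can fail the center-inside test; paint the
    # voxel chain along the cap axis so the apex always exists on the grid
    for (t in seq(g$hc, g$h, by = min(spacing_nm) / 2)) {
      pt <- g$B + g$u * t
      vi <- round(pt[c(2, 1, 3)] / spacing_nm) + 1
      if (all(vi >= 1) && all(vi <= dims)) {
        labels[vi[1], vi[2], vi[3]] <- NC_LABELS[["pillar"]]
        pillar_id_grid[vi[1], vi[2], vi[3]] <- pillars$pillar_id[ri]
      }
    }
  }

  volume <- label_volume(labels, spacing_nm, pillar_ids = pillar_id_grid)

  voxvol_um3 <- prod(spacing_nm) / 1e9
  gt_cells <- lapply(seq_along(cells), function(ci) {
    list(cell = cells[[ci]], reference = reference_cells[[ci]],
         true_surface_area_um2 = cells[[ci]]$surface_area_um2,
         true_volume_um3 = cells[[ci]]$volume_um3,
         reference_volume_um3 = reference_cells[[ci]]$volume_um3,
         voxel_volume_um3 = cell_voxels[ci] * voxvol_um3)
  })

  gt <- list(cells = gt_cells, pillars = pillars,
             interactions = gt_int,
             slice_offsets = NULL,
             spacing_nm = spacing_nm,
             substrate_top_nm = sub_top,
             shell_thickness_nm = shell_thickness_nm)

  if (measure_realized && nrow(gt_int) > 0)
    gt <- measure_ground_truth(volume, gt)

  list(volume = volume, ground_truth = gt)
}

closest_on_segment <- function(p, seg) {
  ab <- seg$b - seg$a
  ab2 <- sum(ab^2)
  if (ab2 == 0) return(seg$a)
  t <- sum((p - seg$a) * ab) / ab2
  seg$a + min(max(t, 0), 1) * ab
}

#' Measure realized interaction values on a pristine phantom grid
#'
#' Fills `realized_class`, `realized_depth_nm` and
#' `realized_tip_contact_area_nm2` in the ground truth by measuring the
#' uncorrupted label volume: depths from the anisotropic interior distance
#' field, contact areas from the extracted envelope and pillar meshes.
#'
#' @param volume pristine [label_volume()] with `pillar_ids`.
#' @param gt ground-truth list from [compose_scene()].
#' @return the augmented ground-truth list.
#' @export
measure_ground_truth <- function(volume, gt) {
  ia <- interior_analysis(volume)
  depth <- ia$depth
  eps <- 2.5 * max(volume$spacing_nm)
  # contact areas are measured on the closed interior surface: the
  # apex-scale contact patch, not the walls of a penetration channel
  cell_meshes <- lapply(seq_along(gt$cells), function(ci)
    extract_surface(volume, cell_interior_mask(volume, gt, ci, ia$closed),
                    smooth_iterations = 20))
  ref_meshes <- lapply(seq_along(gt$cells), function(ci)
    voxelized_cell_mesh(gt$cells[[ci]]$cell, volume))
  gi <- gt$interactions
  gi$realized_depth_nm <- NA_real_
  gi$realized_deformation_depth_nm <- NA_real_
  gi$realized_tip_contact_area_nm2 <- NA_real_
  gi$realized_class <- NA_character_
  for (k in seq_len(nrow(gi))) {
    pid <- gi$pillar_id[k]
    pm <- volume$pillar_ids == pid
    if (!any(pm)) next
    gi$realized_depth_nm[k] <- max(depth[pm])
    # raw binary marching: the antialias prefilter suppresses voxel-thin
    # structures, and pillar tips are exactly that
    pmesh <- extract_surface(volume, pm, object_id = pid,
                             antialias = FALSE, smooth_iterations = 0)
    ca <- tip_contact_area(cell_meshes[[gi$cell_id[k]]], pmesh,
                           epsilon_nm = eps)
    gi$realized_tip_contact_area_nm2[k] <- ca$tip_contact_area_nm2
    gi$realized_deformation_depth_nm[k] <-
      if (gi$intended_class[k] == "deformation")
        deformation_depth(cell_meshes[[gi$cell_id[k]]],
                          ref_meshes[[gi$cell_id[k]]],
                          ca$contact_centroid_nm)
      else 0
    deficit <- assess_volume_deficit(
      gt$cells[[gi$cell_id[k]]]$voxel_volume_um3,
      gt$cells[[gi$cell_id[k]]]$reference_volume_um3)
    gi$realized_class[k] <- if (gi$realized_depth_nm[k] > 0 && deficit >= 0.2)
      "rupture"
    else if (gi$realized_depth_nm[k] > 0) "penetration"
    else gi$intended_class[k]
  }
  gt$interactions <- gi
  gt
}

# logical mask of one cell's interior (envelope + cytosol by default, or a
# supplied base mask), split by proximity to the cell skeletons when several
# cells share the scene
cell_interior_mask <- function(volume, gt, ci, base_mask = NULL) {
  inter <- if (!is.null(base_mask)) base_mask else
    volume$labels == NC_LABELS[["envelope"]] |
      volume$labels == NC_LABELS[["cytosol"]]
  if (length(gt$cells) == 1) return(inter)
  dims <- dim(volume$labels)
  sp <- volume$spacing_nm
  idx <- which(inter)
  iy <- (idx - 1) %% dims[1]
  ix <- ((idx - 1) %/% dims[1]) %% dims[2]
  iz <- (idx - 1) %/% (dims[1] * dims[2])
  P <- cbind(ix * sp[2], iy * sp[1], iz * sp[3])
  dmat <- vapply(gt$cells, function(gc)
    dist_to_segment(P, cell_segment(gc$cell)), numeric(nrow(P)))
  nearest <- max.col(-dmat)
  out <- array(FALSE, dims)
  out[idx[nearest == ci]] <- TRUE
  out
}
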