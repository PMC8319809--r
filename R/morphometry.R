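#' Mesh surface area
#'
#' Sum of triangle areas, converted to square microns. Degenerate faces
#' contribute zero; NaN/NA vertices are a data error.
#'
#' @param mesh a [tri_mesh()] in nm coordinates.
#' @return surface area in um^2.
#' @export
surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$faces) == 0) return(0)
  if (anyNA(mesh$vertices) || any(!is.finite(mesh$vertices)))
    stop("mesh contains non-finite vertices")
  sum(face_areas(mesh)) / 1e6
}

#' Enclosed mesh volume
#'
#' Divergence-theorem signed tetrahedron sum over a watertight mesh. A
#' negative signed volume means the mesh is inward-oriented: the magnitude
#' is returned with an orientation warning.
#'
#' @param mesh a watertight [tri_mesh()] in nm coordinates.
#' @return enclosed volume in um^3.
#' @export
enclosed_volume <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  open <- open_edge_count(mesh)
  if (open > 0)
    stop("mesh is not watertight: ", open, " open edges")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  d <- v[f[, 3], , drop = FALSE]
  signed <- sum(a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) +
                  a[, 2] * (b[, 3] * d[, 1] - b[, 1] * d[, 3]) +
                  a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
  if (signed < 0)
    warning("mesh is inward-oriented; returning |volume|")
  abs(signed) / 1e9
}

#' Interior depth field of the cell
#'
#' For every voxel inside the cell the anisotropic Euclidean distance (nm)
#' to the nearest exterior voxel; 0 outside. The cell interior is the
#' envelope + cytosol mask after a morphological closing with
#' `close_radius_nm`, which seals the narrow channels left where
#' penetrating pillars locally open the envelope, so that pillar voxels
#' past the envelope surface lie inside the field's support and their depth
#' measures how far the tip sits inside the cell.
#'
#' @param volume a [label_volume()].
#' @param close_radius_nm closing ball radius; must exceed the pillar tip
#'   radius to seal penetration channels, and stay well below the cell
#'   radius so real surface shape is preserved.
#' @return numeric 3D array of depths (nm), same dim as the volume.
#' @export
interior_depth_field <- function(volume, close_radius_nm = 60) {
  interior_analysis(volume, close_radius_nm)$depth
}

# closed interior mask and its depth field in one pass
interior_analysis <- function(volume, close_radius_nm = 60) {
  stopifnot(inherits(volume, "label_volume"))
  dims <- dim(volume$labels)
  mask <- volume$labels == NC_LABELS[["envelope"]] |
    volume$labels == NC_LABELS[["cytosol"]]
  if (!any(mask)) stop("cell interior is empty")
  sp <- volume$spacing_nm
  pad_dims <- dims + 2L
  pm <- array(0L, pad_dims)
  pm[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask
  if (close_radius_nm > 0) {
    d_to_mask <- .edt3d(1L - pm, sp)
    dil <- array(as.integer(d_to_mask <= close_radius_nm), pad_dims)
    d_in_dil <- .edt3d(dil, sp)
    closed <- array(as.integer(d_in_dil > close_radius_nm), pad_dims)
  } else {
    closed <- pm
  }
  depth <- .edt3d(closed, sp)
  core <- list(2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1))
  list(depth = depth[core[[1]], core[[2]], core[[3]]],
       closed = array(closed[core[[1]], core[[2]], core[[3]]] > 0, dims))
}

#' Penetration depth of a pillar
#'
#' The maximum of the interior depth field over the pillar's voxels - the
#' depth of the apex inside the cell; 0 when no pillar voxel is interior.
#' Depths below `min_depth_nm` are reported as 0 (below measurement
#' resolution).
#'
#' @param pillar_mask logical/0-1 array of the pillar's voxels.
#' @param depth_field from [interior_depth_field()], same grid.
#' @param min_depth_nm resolution floor.
#' @return penetration depth in nm.
#' @export
penetration_depth <- function(pillar_mask, depth_field, min_depth_nm = 0) {
  stopifnot(identical(dim(pillar_mask), dim(depth_field)))
  sel <- pillar_mask != 0
  if (!any(sel)) stop("pillar mask is empty")
  d <- max(depth_field[sel])
  if (d < min_depth_nm) 0 else d
}

# dominant axis of a pillar mesh: principal direction of its vertices,
# oriented upward (toward +y)
pillar_axis <- function(mesh) {
  v <- mesh$vertices
  if (nrow(v) < 3) return(c(0, 1, 0))
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  ax <- pc$rotation[, 1]
  if (ax[2] < 0) ax <- -ax
  ax
}

#' Nanopillar tip contact area against the envelope
#'
#' Sums the areas of envelope faces whose centroid lies within `epsilon_nm`
#' of the pillar surface (nearest-point distance to the pillar mesh).
#' The contact is classified as `tip` when the majority (by area) of the
#' nearest pillar points sit within the apex cap - the top
#' `1 - tip_fraction` of the pillar's height along its dominant axis -
#' and as `sidewall` otherwise. Also returns the area-weighted centroid of
#' the contact patch and its height fraction on the cell (0 = cell bottom).
#'
#' @param envelope a [tri_mesh()] of the cell surface.
#' @param pillar a [tri_mesh()] of one nanopillar.
#' @param epsilon_nm contact distance; the default used throughout the
#'   package is twice the largest voxel spacing (one-voxel surface
#'   quantization on each mesh).
#' @param tip_fraction height fraction above which pillar surface counts as
#'   the apex cap.
#' @return a `contact_geometry` list: `pillar_id`, `tip_contact_area_nm2`,
#'   `contact_zone`, `contact_centroid_nm`, `contact_height_fraction`,
#'   `epsilon_nm`.
#' @export
tip_contact_area <- function(envelope, pillar, epsilon_nm,
                             tip_fraction = 0.9) {
  stopifnot(inherits(envelope, "tri_mesh"), inherits(pillar, "tri_mesh"),
            epsilon_nm > 0)
  out <- list(pillar_id = pillar$object_id, tip_contact_area_nm2 = 0,
              contact_zone = NA_character_,
              contact_centroid_nm = c(NA_real_, NA_real_, NA_real_),
              contact_height_fraction = NA_real_,
              epsilon_nm = epsilon_nm)
  class(out) <- "contact_geometry"
  if (nrow(envelope$faces) == 0 || nrow(pillar$faces) == 0) return(out)
  cen <- face_centroids(envelope)
  ar <- face_areas(envelope)
  # cull centroids outside the pillar's epsilon-inflated bounding box: they
  # cannot be within epsilon of its surface
  bb_lo <- apply(pillar$vertices, 2, min) - 1.5 * epsilon_nm
  bb_hi <- apply(pillar$vertices, 2, max) + 1.5 * epsilon_nm
  near <- cen[, 1] >= bb_lo[1] & cen[, 1] <= bb_hi[1] &
    cen[, 2] >= bb_lo[2] & cen[, 2] <= bb_hi[2] &
    cen[, 3] >= bb_lo[3] & cen[, 3] <= bb_hi[3]
  if (!any(near)) return(out)
  res <- .points_to_mesh(cen[near, , drop = FALSE],
                         pillar$vertices, pillar$faces)
  sel <- rep(FALSE, nrow(cen))
  sel[near] <- res$distance <= epsilon_nm
  if (!any(sel)) return(out)
  res <- list(distance = res$distance[res$distance <= epsilon_nm],
              nearest = res$nearest[res$distance <= epsilon_nm, , drop = FALSE])
  w <- ar[sel]
  out$tip_contact_area_nm2 <- sum(w)
  ctr <- colSums(cen[sel, , drop = FALSE] * w) / sum(w)
  out$contact_centroid_nm <- ctr
  ax <- pillar_axis(pillar)
  t_all <- pillar$vertices %*% ax
  t_near <- res$nearest %*% ax
  f <- (t_near - min(t_all)) / max(max(t_all) - min(t_all), 1e-9)
  tip_area <- sum(w[f >= tip_fraction])
  out$contact_zone <- if (tip_area >= 0.5 * sum(w)) "tip" else "sidewall"
  ylim <- range(envelope$vertices[, 2])
  out$contact_height_fraction <-
    (ctr[2] - ylim[1]) / max(ylim[2] - ylim[1], 1e-9)
  out
}

#' Deformation depth at a contact
#'
#' Maximum inward (toward the cell center) deviation of the actual envelope
#' vertices from a reference surface, within `radius_nm` of the contact
#' centroid; 0 when the deviation is only outward. Inward/outward is decided
#' by the outward normal of the nearest reference face. The maximum is
#' evaluated robustly (upper `quantile` of the inward deviations over the
#' patch) so that a few vertices of voxel-scale carving at a touching tip do
#' not read as an indentation; a genuine dimple moves most of the patch.
#'
#' @param actual actual envelope [tri_mesh()].
#' @param reference reference (undeformed) envelope [tri_mesh()]; on
#'   phantoms this is the voxelized ideal cell, on real data a heavily
#'   smoothed copy of the envelope (see [smooth_reference()]).
#' @param contact_centroid_nm 3-vector, from [tip_contact_area()].
#' @param radius_nm patch radius around the centroid.
#' @param quantile upper quantile of inward deviations reported as the
#'   depth (1 = strict maximum).
#' @return deformation depth in nm.
#' @export
deformation_depth <- function(actual, reference, contact_centroid_nm,
                              radius_nm = 150, quantile = 0.95) {
  stopifnot(inherits(actual, "tri_mesh"), inherits(reference, "tri_mesh"))
  if (anyNA(contact_centroid_nm)) return(0)
  v <- actual$vertices
  d2 <- (v[, 1] - contact_centroid_nm[1])^2 +
    (v[, 2] - contact_centroid_nm[2])^2 +
    (v[, 3] - contact_centroid_nm[3])^2
  sel <- d2 <= radius_nm^2
  if (!any(sel)) return(0)
  p <- v[sel, , drop = FALSE]
  res <- .points_to_mesh(p, reference$vertices, reference$faces)
  nrm <- face_cross(reference)[res$face, , drop = FALSE]
  side <- rowSums((p - res$nearest) * nrm)
  dev <- ifelse(side < 0, res$distance, 0)
  if (all(dev == 0)) return(0)
  as.numeric(stats::quantile(dev, quantile))
}

#' Smoothed-reference fallback for deformation measurements
#'
#' A heavily smoothed (plain shrinking Laplacian) copy of the envelope,
#' usable as the reference surface when no phantom ground truth exists.
#' This is an approximation: it flattens dimples but also slightly shrinks
#' the whole surface.
#'
#' @param envelope a [tri_mesh()].
#' @param iterations Laplacian passes.
#' @return the smoothed [tri_mesh()].
#' @export
smooth_reference <- function(envelope, iterations = 60) {
  taubin_smooth(envelope, iterations = iterations, lambda = 0.5, mu = 0)
}

#' Characterize a nanopillar field
#'
#' Density, height and tip-diameter moments, either directly from a pillar
#' spec table or measured from a label volume: per 26-connected pillar
#' component, height is the extent along the component's dominant axis
#' above the substrate plane, and tip diameter is the equivalent-circle
#' diameter of the cross section at 95% of the height.
#'
#' @param x pillar spec `data.frame` (from [sample_pillar_field()]) or a
#'   [label_volume()].
#' @param field_area_um2 field area; required for a spec table, derived
#'   from the grid extent for a volume.
#' @param min_voxels component size floor when measuring from a volume.
#' @return list with `density_per_um2`, `height_mean_nm`, `height_sd_nm`,
#'   `tip_diameter_mean_nm`, `tip_diameter_sd_nm`, `n_pillars`.
#' @export
characterize_field <- function(x, field_area_um2 = NULL, min_voxels = 30) {
  if (is.data.frame(x)) {
    if (is.null(field_area_um2)) stop("field_area_um2 is required")
    n <- nrow(x)
    if (n == 0)
      return(list(density_per_um2 = 0, height_mean_nm = NA_real_,
                  height_sd_nm = NA_real_, tip_diameter_mean_nm = NA_real_,
                  tip_diameter_sd_nm = NA_real_, n_pillars = 0L))
    return(list(density_per_um2 = n / field_area_um2,
                height_mean_nm = mean(x$height_nm),
                height_sd_nm = if (n > 1) sd(x$height_nm) else 0,
                tip_diameter_mean_nm = mean(x$tip_diameter_nm),
                tip_diameter_sd_nm = if (n > 1) sd(x$tip_diameter_nm) else 0,
                n_pillars = n))
  }
  stopifnot(inherits(x, "label_volume"))
  sp <- x$spacing_nm
  dims <- dim(x$labels)
  if (is.null(field_area_um2))
    field_area_um2 <- (dims[2] * sp[2]) * (dims[3] * sp[3]) / 1e6
  sub <- which(x$labels == NC_LABELS[["substrate"]], arr.ind = TRUE)
  sub_top <- if (nrow(sub) > 0) max(sub[, 1]) * sp[1] else 0
  comps <- split_pillar_components(x, min_voxels = min_voxels)
  if (length(comps) == 0)
    return(list(density_per_um2 = 0, height_mean_nm = NA_real_,
                height_sd_nm = NA_real_, tip_diameter_mean_nm = NA_real_,
                tip_diameter_sd_nm = NA_real_, n_pillars = 0L))
  hs <- numeric(length(comps)); td <- numeric(length(comps))
  for (k in seq_along(comps)) {
    idx <- which(comps[[k]], arr.ind = TRUE)
    P <- cbind((idx[, 2] - 1) * sp[2], (idx[, 1] - 1) * sp[1],
               (idx[, 3] - 1) * sp[3])
    P <- P[P[, 2] > sub_top, , drop = FALSE]
    if (nrow(P) < 3) { hs[k] <- NA; td[k] <- NA; next }
    pc <- stats::prcomp(P, center = TRUE, scale. = FALSE)
    ax <- pc$rotation[, 1]
    if (ax[2] < 0) ax <- -ax
    t <- as.numeric(P %*% ax)
    hs[k] <- diff(range(t))
    slab <- t >= min(t) + 0.93 * hs[k] & t <= min(t) + 0.97 * hs[k]
    area <- sum(slab) * prod(sp) / (0.04 * hs[k])
    td[k] <- 2 * sqrt(area / pi)
  }
  ok <- is.finite(hs)
  list(density_per_um2 = length(comps) / field_area_um2,
       height_mean_nm = mean(hs[ok]),
       height_sd_nm = if (sum(ok) > 1) sd(hs[ok]) else 0,
       tip_diameter_mean_nm = mean(td[ok]),
       tip_diameter_sd_nm = if (sum(ok) > 1) sd(td[ok]) else 0,
       n_pillars = length(comps))
}
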