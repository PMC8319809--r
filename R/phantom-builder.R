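#' Build a complete ground-truthed phantom scene
#'
#' Convenience builder for study-style scenes: one cell (rod or coccus) over
#' a nanopillar field of a given surface preset, with a requested set of
#' imposed interactions. Contact pillars are placed deterministically under
#' (or, for impedance, beside) the cell and adjusted by [compose_scene()];
#' optional background pillars are sampled from the preset's density and
#' kept clear of the cell so the number of contacts is exactly the number
#' of requested interactions.
#'
#' Default cell dimensions follow the two study organisms: a coccus of 1 um
#' diameter (S. aureus) sectioned at 20 nm, and a 500 nm x 2000 nm rod
#' (E. coli) sectioned at 30 nm.
#'
#' @param preset surface preset name ([surface_preset()]).
#' @param cell_kind `"coccus"` or `"rod"`.
#' @param interactions character vector of interaction classes (defaults
#'   applied: penetration depth 50 nm, deformation depth 60 nm / radius
#'   150 nm, rupture depth 50 nm / deficit 0.3), or a list mixing class
#'   names with partial spec lists, e.g.
#'   `list("none", list(class = "penetration", depth_nm = 40))`.
#' @param seed integer seed (pillar dimensions, background field).
#' @param pixel_size_nm in-plane voxel size; by default 15 nm, refined to
#'   12 nm for presets with tips finer than 40 nm.
#' @param slice_thickness_nm slice thickness; defaults per cell kind.
#' @param cell_width_nm,cell_length_nm cell dimensions (nm).
#' @param with_background sample non-contacting background pillars from the
#'   preset density.
#' @param measure_realized forwarded to [compose_scene()].
#' @return list with `volume`, `ground_truth` (see [compose_scene()]).
#' @export
phantom_scene <- function(preset = "ah-ns-medium",
                          cell_kind = c("coccus", "rod"),
                          interactions = c("penetration", "none"),
                          seed = 1,
                          pixel_size_nm = NULL,
                          slice_thickness_nm = NULL,
                          cell_width_nm = NULL, cell_length_nm = NULL,
                          with_background = FALSE,
                          measure_realized = TRUE) {
  cell_kind <- match.arg(cell_kind)
  set.seed(seed)
  if (is.null(pixel_size_nm)) {
    # sampled so the finest preset's tip radius spans at least one voxel
    params0 <- surface_preset(preset)
    pixel_size_nm <- if (params0$tip_diameter_mean_nm < 40) 12 else 15
  }
  if (is.null(slice_thickness_nm))
    slice_thickness_nm <- if (cell_kind == "coccus") 20 else 30
  if (is.null(cell_width_nm))
    cell_width_nm <- if (cell_kind == "coccus") 1000 else 500
  if (is.null(cell_length_nm))
    cell_length_nm <- if (cell_kind == "coccus") cell_width_nm else 2000
  spacing <- c(pixel_size_nm, pixel_size_nm, slice_thickness_nm)

  specs <- normalize_interactions(interactions)
  n_tip <- sum(vapply(specs, function(s) s$class != "impedance", TRUE))
  n_imp <- length(specs) - n_tip

  params <- surface_preset(preset)
  R <- cell_width_nm / 2
  sub_top <- 60
  clearance <- if (n_tip > 0) params$height_mean_nm else 3 * pixel_size_nm
  cy <- sub_top + clearance + R

  # scene extents (x across the cell, z along the rod axis / milling axis)
  half_x <- R + (if (n_imp > 0) 2 * params$tip_diameter_mean_nm + 200 else 0) + 500
  half_z <- cell_length_nm / 2 + 500
  cx <- half_x; cz <- half_z
  cell <- cell_shape(cell_kind, width_nm = cell_width_nm,
                     length_nm = if (cell_kind == "rod") cell_length_nm else NULL,
                     center_nm = c(cx, cy, cz), long_axis = c(0, 0, 1))

  # deterministic lateral placement of tip-contact pillars under the cell
  golden <- pi * (3 - sqrt(5))
  tipk <- 0
  rows <- list()
  ints <- list()
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    if (s$class == "impedance") {
      side <- if (length(rows) %% 2 == 0) 1 else -1
      bx <- cx + side * (R + params$tip_diameter_mean_nm)
      bz <- cz + (if (length(rows) > 1) (length(rows) - 1) * 60 else 0)
      h <- max(params$height_mean_nm, cy + 100 - sub_top)
    } else {
      tipk <- tipk + 1
      if (cell_kind == "coccus") {
        rr <- 0.45 * R * sqrt(tipk / max(n_tip, 1))
        th <- tipk * golden
        bx <- cx + rr * cos(th)
        bz <- cz + rr * sin(th)
      } else {
        # two staggered rows along the rod axis: keeps neighboring pillar
        # bases separated so each contact stays its own connected component
        bx <- cx + 0.3 * R * (if (tipk %% 2 == 0) 1 else -1)
        bz <- cz + ((tipk - 0.5) / n_tip - 0.5) * 0.95 * (cell_length_nm - cell_width_nm)
      }
      h <- clearance + R  # provisional; compose_scene solves the exact height
    }
    tip <- rtruncnorm_pos(1, params$tip_diameter_mean_nm,
                          params$tip_diameter_sd_nm)
    rows[[k]] <- data.frame(pillar_id = k, base_x_nm = bx, base_z_nm = bz,
                            axis_x = 0, axis_y = 1, axis_z = 0,
                            height_nm = h, tip_diameter_nm = tip,
                            base_diameter_nm = params$base_diameter_factor * tip)
    ints[[k]] <- interaction_spec(k, s$class, depth_nm = s$depth_nm,
                                  dimple_radius_nm = s$dimple_radius_nm,
                                  volume_deficit_fraction = s$volume_deficit_fraction)
  }
  pillars <- do.call(rbind, rows)

  if (with_background) {
    bg_params <- params
    bg_params$field_size_um <- c(2 * half_x, 2 * half_z) / 1000
    bg <- sample_pillar_field(bg_params, seed = seed + 1)
    if (nrow(bg) > 0) {
      keep <- vapply(seq_len(nrow(bg)), function(i) {
        g <- pillar_geom(bg[i, ], sub_top)
        clear_of_cell(g, cell, 2 * max(spacing)) &&
          min((pillars$base_x_nm - bg$base_x_nm[i])^2 +
                (pillars$base_z_nm - bg$base_z_nm[i])^2) >
            (params$min_spacing_nm / 2)^2
      }, TRUE)
      bg <- bg[keep, , drop = FALSE]
      if (nrow(bg) > 0) {
        bg$pillar_id <- nrow(pillars) + seq_len(nrow(bg))
        pillars <- rbind(pillars, bg)
      }
    }
  }

  scene_y <- max(cy + R, sub_top + max(pillars$height_nm)) + 10 * pixel_size_nm
  compose_scene(cells = list(cell), pillars = pillars, interactions = ints,
                spacing_nm = spacing,
                scene_size_nm = c(scene_y, 2 * half_x, 2 * half_z),
                substrate_thickness_nm = sub_top,
                measure_realized = measure_realized)
}

# does the pillar stay clear of the cell surface by at least `margin`?
clear_of_cell <- function(g, cell, margin) {
  seg <- cell_segment(cell)
  ts <- seq(0, g$h, length.out = 40)
  P <- cbind(g$B[1] + g$u[1] * ts, g$B[2] + g$u[2] * ts,
             g$B[3] + g$u[3] * ts)
  min(dist_to_segment(P, seg)) > cell$width_nm / 2 + g$rb + margin
}

interaction_defaults <- list(
  none = list(depth_nm = 0, dimple_radius_nm = 150, volume_deficit_fraction = 0),
  deformation = list(depth_nm = 60, dimple_radius_nm = 200,
                     volume_deficit_fraction = 0),
  penetration = list(depth_nm = 60, dimple_radius_nm = 150,
                     volume_deficit_fraction = 0),
  rupture = list(depth_nm = 60, dimple_radius_nm = 150,
                 volume_deficit_fraction = 0.3),
  impedance = list(depth_nm = 0, dimple_radius_nm = 150,
                   volume_deficit_fraction = 0))

normalize_interactions <- function(interactions) {
  if (is.character(interactions)) interactions <- as.list(interactions)
  lapply(interactions, function(it) {
    if (is.character(it)) it <- list(class = it)
    stopifnot(!is.null(it$class), it$class %in% names(interaction_defaults))
    modifyList(c(list(class = it$class), interaction_defaults[[it$class]]),
               it)
  })
}
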