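#' Quantify all pillar-cell contacts in a segmented volume
#'
#' The measurement core of the pipeline: identifies cells (26-connected
#' components of the morphologically closed envelope + cytosol mask) and
#' pillars ([split_pillar_components()]), meshes them, measures contact
#' geometry ([tip_contact_area()]), penetration depths (interior distance
#' field) and deformation depths (against the phantom reference cell when
#' ground truth is available, else a smoothed-envelope fallback), assesses
#' per-cell volume deficits, classifies every contact and aggregates
#' per-cell reports.
#'
#' @param volume a segmented [label_volume()].
#' @param ground_truth optional phantom ground truth (supplies reference
#'   cells for deformation and reference volumes for rupture).
#' @param thresholds a [classification_thresholds()]; the default derives
#'   `epsilon_nm` as twice the largest voxel spacing.
#' @param reference_volume_um3 expected undeformed cell volume for deficit
#'   assessment when no ground truth exists (e.g. 0.35 for a coccus,
#'   0.75 for a rod); `NULL` disables rupture calls on non-phantom data.
#' @param min_cell_voxels,min_pillar_voxels component size floors.
#' @param deformation_radius_nm patch radius for deformation measurement.
#' @return list with `cells` (per-cell morphometrics and meshes), `records`
#'   (all contact records, with `cell_id`), `reports` (per-cell
#'   [build_cell_report()]), `pillar_meshes`.
#' @export
quantify_volume <- function(volume, ground_truth = NULL,
                            thresholds = NULL,
                            reference_volume_um3 = NULL,
                            min_cell_voxels = 200,
                            min_pillar_voxels = 30,
                            deformation_radius_nm = 120) {
  stopifnot(inherits(volume, "label_volume"))
  sp <- volume$spacing_nm
  eps <- 2.5 * max(sp)
  if (is.null(thresholds))
    thresholds <- classification_thresholds(
      tau_deform_nm = max(15, max(sp)), epsilon_nm = eps)
  if (!any(volume$labels == NC_LABELS[["envelope"]] |
             volume$labels == NC_LABELS[["cytosol"]]))
    return(list(cells = list(), records = NULL, reports = list(),
                pillar_meshes = list(), thresholds = thresholds,
                volume_deficits = numeric(0)))
  ia <- interior_analysis(volume)
  depth <- ia$depth

  # cells: components of the closed interior
  cc <- .cc3d(array(as.integer(ia$closed), dim(ia$closed)), 26L)
  sizes <- tabulate(cc[cc > 0])
  cids <- which(sizes >= min_cell_voxels)
  cids <- cids[order(sizes[cids], decreasing = TRUE)]
  cells <- lapply(seq_along(cids), function(i) {
    mask <- cc == cids[i]
    mesh <- extract_surface(volume, mask, object_id = i,
                            smooth_iterations = 20)

    sa <- surface_area(mesh)
    vol <- enclosed_volume(mesh)
    idx <- which(mask, arr.ind = TRUE)
    center <- c(mean((idx[, 2] - 1) * sp[2]), mean((idx[, 1] - 1) * sp[1]),
                mean((idx[, 3] - 1) * sp[3]))
    list(cell_id = i, mask = mask, mesh = mesh,
         envelope_surface_area_um2 = sa, cell_volume_um3 = vol,
         center_nm = center)
  })

  # reference surface and reference volume per cell
  refs <- lapply(cells, function(cl) {
    if (!is.null(ground_truth)) {
      gi <- which.min(vapply(ground_truth$cells, function(gc)
        sum((gc$cell$center_nm - cl$center_nm)^2), numeric(1)))
      gc <- ground_truth$cells[[gi]]
      list(mesh = voxelized_cell_mesh(gc$cell, volume),
           reference_volume_um3 = gc$reference_volume_um3)
    } else {
      list(mesh = smooth_reference(cl$mesh),
           reference_volume_um3 = reference_volume_um3)
    }
  })
  deficits <- vapply(seq_along(cells), function(i) {
    rv <- refs[[i]]$reference_volume_um3
    if (is.null(rv)) 0 else
      assess_volume_deficit(cells[[i]]$cell_volume_um3, rv)
  }, numeric(1))

  comps <- split_pillar_components(volume, min_voxels = min_pillar_voxels)
  # penetration is topological: the pillar has pierced through the envelope
  # when its voxels sit directly against cytosol (the depth field then
  # quantifies how far). A tangent or deforming tip stays separated from the
  # cytosol by the envelope shell.
  cyto_adjacent <- touches_label(volume$labels, NC_LABELS[["cytosol"]],
                                 connectivity = 26)
  pillar_meshes <- list()
  records <- list()
  for (pid in seq_along(comps)) {
    pmask <- comps[[pid]]
    # raw binary marching: the antialias prefilter suppresses voxel-thin
    # pillar tips (see the ground-truth measurement, which matches)
    pmesh <- extract_surface(volume, pmask, object_id = pid,
                             antialias = FALSE, smooth_iterations = 0)
    pillar_meshes[[pid]] <- pmesh
    geoms <- lapply(cells, function(cl)
      tip_contact_area(cl$mesh, pmesh, epsilon_nm = thresholds$epsilon_nm))
    areas <- vapply(geoms, function(g) g$tip_contact_area_nm2, numeric(1))
    if (all(areas <= 0)) next
    ci <- which.max(areas)
    geom <- geoms[[ci]]
    pen <- if (any(pmask & cyto_adjacent))
      penetration_depth(pmask, depth) else 0
    geom$penetration_depth_nm <- pen
    geom$deformation_depth_nm <- if (pen > 0) 0 else
      deformation_depth(cells[[ci]]$mesh, refs[[ci]]$mesh,
                        geom$contact_centroid_nm,
                        radius_nm = deformation_radius_nm)
    rec <- classify_contact(geom, cell_volume_deficit = deficits[ci],
                            thresholds = thresholds)
    if (is.null(rec)) next
    rec$cell_id <- ci
    idx <- which(pmask, arr.ind = TRUE)
    top <- idx[which.max(idx[, 1]), ]
    rec$apex_x_nm <- (top[2] - 1) * sp[2]
    rec$apex_y_nm <- (top[1] - 1) * sp[1]
    rec$apex_z_nm <- (top[3] - 1) * sp[3]
    records[[length(records) + 1]] <- rec
  }
  records <- if (length(records) > 0) do.call(rbind, records) else NULL

  reports <- lapply(cells, function(cl) {
    rc <- if (!is.null(records)) records[records$cell_id == cl$cell_id, ] else NULL
    build_cell_report(cl$cell_id, cl$envelope_surface_area_um2,
                      cl$cell_volume_um3, rc)
  })

  list(cells = lapply(cells, function(cl) cl[setdiff(names(cl), "mask")]),
       records = records, reports = reports,
       pillar_meshes = pillar_meshes, thresholds = thresholds,
       volume_deficits = deficits)
}

# voxels whose neighborhood (6- or 26-connected) contains the given label
touches_label <- function(labels, label, connectivity = 6) {
  m <- array(as.integer(labels == label), dim(labels))
  dil <- .sepconv3(m, c(1, 1, 1))
  if (connectivity == 26) array(dil > 0, dim(m))
  else {
    out <- array(FALSE, dim(m))
    d <- dim(m)
    mm <- m > 0
    out[-d[1], , ] <- out[-d[1], , ] | mm[-1, , ]
    out[-1, , ] <- out[-1, , ] | mm[-d[1], , ]
    out[, -d[2], ] <- out[, -d[2], ] | mm[, -1, ]
    out[, -1, ] <- out[, -1, ] | mm[, -d[2], ]
    out[, , -d[3]] <- out[, , -d[3]] | mm[, , -1]
    out[, , -1] <- out[, , -1] | mm[, , -d[3]]
    out
  }
}

# voxelize an ideal cell on the grid of `volume` and mesh it: the phantom
# reference surface for deformation measurements
voxelized_cell_mesh <- function(cell, volume) {
  dims <- dim(volume$labels)
  sp <- volume$spacing_nm
  seg <- cell_segment(cell)
  ys <- (seq_len(dims[1]) - 1) * sp[1]
  xs <- (seq_len(dims[2]) - 1) * sp[2]
  zs <- (seq_len(dims[3]) - 1) * sp[3]
  ny <- dims[1]; nx <- dims[2]; nz <- dims[3]
  P <- cbind(rep(xs, each = ny, times = nz),
             rep(ys, times = nx * nz),
             rep(zs, each = ny * nx))
  inside <- dist_to_segment(P, seg) <= cell$width_nm / 2
  mask <- array(inside, dims)
  extract_surface(label_volume(array(0L, dims), sp), mask)
}

#' Compare a measured result to phantom ground truth
#'
#' Matches measured pillar components to ground-truth interactions by apex
#' proximity and tabulates intended vs assigned classes alongside depth and
#' contact-area errors, plus per-cell surface-area and volume errors.
#'
#' @param result from [quantify_volume()].
#' @param ground_truth from [compose_scene()] / [phantom_scene()].
#' @param match_radius_nm maximum apex distance for a match.
#' @return list with `contacts` (one row per ground-truth interaction) and
#'   `cells` (one row per ground-truth cell).
#' @export
compare_to_ground_truth <- function(result, ground_truth,
                                    match_radius_nm = 300) {
  gi <- ground_truth$interactions
  rec <- result$records
  rows <- lapply(seq_len(nrow(gi)), function(k) {
    out <- data.frame(pillar_id = gi$pillar_id[k],
                      intended_class = gi$intended_class[k],
                      realized_class = gi$realized_class[k] %||% NA_character_,
                      intended_depth_nm = gi$intended_depth_nm[k],
                      realized_depth_nm = gi$realized_depth_nm[k] %||% NA_real_,
                      realized_deformation_depth_nm =
                        gi$realized_deformation_depth_nm[k] %||% NA_real_,
                      realized_tip_contact_area_nm2 =
                        gi$realized_tip_contact_area_nm2[k] %||% NA_real_,
                      assigned_class = NA_character_,
                      measured_depth_nm = NA_real_,
                      measured_tip_contact_area_nm2 = NA_real_,
                      stringsAsFactors = FALSE)
    if (is.null(rec) || nrow(rec) == 0) return(out)
    d <- sqrt((rec$apex_x_nm - gi$apex_x_nm[k])^2 +
                (rec$apex_y_nm - gi$apex_y_nm[k])^2 +
                (rec$apex_z_nm - gi$apex_z_nm[k])^2)
    j <- which.min(d)
    if (d[j] > match_radius_nm) return(out)
    out$assigned_class <- rec$interaction_class[j]
    out$measured_depth_nm <- if (rec$interaction_class[j] %in%
                                   c("penetration", "rupture"))
      rec$penetration_depth_nm[j] else rec$deformation_depth_nm[j]
    out$measured_tip_contact_area_nm2 <- rec$tip_contact_area_nm2[j]
    out
  })
  contacts <- do.call(rbind, rows)

  cells <- do.call(rbind, lapply(seq_along(ground_truth$cells), function(ci) {
    gc <- ground_truth$cells[[ci]]
    mi <- which.min(vapply(result$cells, function(cl)
      sum((cl$center_nm - gc$cell$center_nm)^2), numeric(1)))
    data.frame(cell_id = ci,
               true_surface_area_um2 = gc$true_surface_area_um2,
               measured_surface_area_um2 =
                 result$cells[[mi]]$envelope_surface_area_um2,
               true_volume_um3 = gc$true_volume_um3,
               measured_volume_um3 = result$cells[[mi]]$cell_volume_um3)
  }))
  list(contacts = contacts, cells = cells)
}

#' Run the full pipeline
#'
#' Orchestrates simulate - process - reconstruct - quantify - classify -
#' report with one seed, writing every artifact (stack TIFF, label TIFFs,
#' OBJ meshes, contact records, reports, ground truth, a ground-truth
#' comparison, and a run log with all resolved parameters) into `out_dir`.
#' Any stage failure aborts with the stage name; artifacts of completed
#' stages persist.
#'
#' @param config a list; see Details. Minimal usage:
#'   `run_pipeline(list(out_dir = tempfile(), seed = 1))`.
#' @details Recognized entries (with defaults): `mode` ("simulate" or
#'   "from_stack"), `preset` ("pe-ns-short"), `cell_kind` ("rod"),
#'   `interactions` (class vector, see [phantom_scene()]), `seed` (1),
#'   `pixel_size_nm` (15), `with_background` (FALSE), `acquisition` (list:
#'   `tilt_deg` 52, `drift_sd_px` 2, `noise_sd` 5, `curtaining_amplitude`
#'   0), `segmentation` (list: `thresholds` fixed default cuts or "auto",
#'   `min_component_voxels` 30), `stack_path` (for `from_stack`),
#'   `reference_volume_um3`, `out_dir` (required).
#' @return list with `reports`, `records`, `comparison` (when ground truth
#'   exists) and `paths` of written artifacts, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- modifyList(list(
    mode = "simulate", preset = "pe-ns-short", cell_kind = "rod",
    interactions = c("penetration", "penetration", rep("none", 4)),
    seed = 1, pixel_size_nm = NULL, cell_width_nm = NULL,
    cell_length_nm = NULL, with_background = FALSE,
    acquisition = list(), segmentation = list(),
    stack_path = NULL, reference_volume_um3 = NULL, out_dir = NULL),
    config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log <- list(config = cfg,
              package_version = as.character(utils::packageVersion("nanocontact")),
              r_version = R.version.string,
              started = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gt <- NULL
  if (cfg$mode == "simulate") {
    scene <- stage("simulate", {
      sc <- if (identical(cfg$cell_kind, "none")) {
        # bare nanotopography, no cell: pillars only
        prm <- surface_preset(cfg$preset, field_size_um = c(2, 2))
        compose_scene(list(), sample_pillar_field(prm, seed = cfg$seed),
                      list(), spacing_nm = c(15, 15, 30),
                      scene_size_nm = c(prm$height_mean_nm +
                                          3 * prm$height_sd_nm + 200,
                                        2000, 2000))
      } else phantom_scene(preset = cfg$preset, cell_kind = cfg$cell_kind,
                           interactions = cfg$interactions, seed = cfg$seed,
                           pixel_size_nm = cfg$pixel_size_nm,
                           cell_width_nm = cfg$cell_width_nm,
                           cell_length_nm = cfg$cell_length_nm,
                           with_background = isTRUE(cfg$with_background))
      acq <- do.call(acquisition_params, modifyList(
        list(tilt_deg = 52, drift_sd_px = 2, noise_sd = 5,
             slice_thickness_nm = sc$volume$spacing_nm[3],
             pixel_size_nm = cfg$pixel_size_nm),
        cfg$acquisition))
      sim <- simulate_acquisition(sc$volume, acq, seed = cfg$seed + 1,
                                  ground_truth = sc$ground_truth)
      paths$truth_labels <- file.path(cfg$out_dir, "labels_truth.tif")
      write_label_volume(sc$volume, paths$truth_labels)
      paths$stack <- file.path(cfg$out_dir, "stack.tif")
      write_stack(sim$stack, paths$stack)
      paths$ground_truth <- file.path(cfg$out_dir, "ground_truth.json")
      jsonlite::write_json(serializable_gt(sim$ground_truth),
                           paths$ground_truth, auto_unbox = TRUE, digits = NA,
                           na = "null")
      list(stack = sim$stack, gt = sim$ground_truth, noise = acq$noise_sd)
    })
    stack <- scene$stack
    gt <- scene$gt
    noisy <- scene$noise > 0
  } else {
    stack <- stage("read", read_stack(cfg$stack_path))
    noisy <- TRUE
  }

  volume <- stage("process", {
    al <- align_stack(stack)
    st <- correct_foreshortening(crop_canvas(al$stack))
    seg_args <- modifyList(list(denoise = noisy), cfg$segmentation)
    seg_args$stack <- st
    v <- do.call(segment_labels, seg_args)
    paths$labels <- file.path(cfg$out_dir, "labels.tif")
    write_label_volume(v, paths$labels)
    paths$alignment <- file.path(cfg$out_dir, "alignment.json")
    jsonlite::write_json(list(offsets = al$alignment$offsets,
                              confidence = al$alignment$confidence),
                         paths$alignment, digits = NA)
    v
  })

  result <- stage("quantify", quantify_volume(
    volume, ground_truth = gt,
    reference_volume_um3 = cfg$reference_volume_um3))

  stage("reconstruct", {
    mesh_dir <- file.path(cfg$out_dir, "meshes")
    dir.create(mesh_dir, showWarnings = FALSE)
    for (cl in result$cells)
      write_obj(cl$mesh, file.path(mesh_dir, sprintf("cell_%d.obj", cl$cell_id)))
    for (i in seq_along(result$pillar_meshes))
      write_obj(result$pillar_meshes[[i]],
                file.path(mesh_dir, sprintf("pillar_%d.obj", i)))
    paths$meshes <- mesh_dir
  })

  stage("report", {
    paths$records <- file.path(cfg$out_dir, "records.json")
    jsonlite::write_json(result$records, paths$records, auto_unbox = TRUE,
                         digits = NA, na = "null", dataframe = "rows")
    paths$reports_csv <- file.path(cfg$out_dir, "reports.csv")
    export_reports(result$reports, paths$reports_csv, "csv")
    paths$reports_json <- file.path(cfg$out_dir, "reports.json")
    export_reports(result$reports, paths$reports_json, "json")
  })

  comparison <- NULL
  if (!is.null(gt) && length(gt$cells) > 0) {
    comparison <- stage("compare", {
      cmp <- compare_to_ground_truth(result, gt)
      paths$comparison <- file.path(cfg$out_dir, "comparison.json")
      jsonlite::write_json(cmp, paths$comparison, auto_unbox = TRUE,
                           digits = NA, na = "null", dataframe = "rows")
      cmp
    })
  }

  log$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC")
  paths$log <- file.path(cfg$out_dir, "run_log.json")
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, na = "null",
                       force = TRUE)
  invisible(list(reports = result$reports, records = result$records,
                 comparison = comparison, paths = paths))
}

# ground truth with cell_shape objects flattened for JSON
serializable_gt <- function(gt) {
  gt$cells <- lapply(gt$cells, function(gc) {
    gc$cell <- unclass(gc$cell)
    gc$reference <- unclass(gc$reference)
    gc
  })
  gt
}
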