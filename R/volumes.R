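#' Labeled voxel volume
#'
#' A 3D integer label grid with physical voxel spacing. The array is indexed
#' `[y, x, z]`: `y` is the in-image vertical axis (height above the
#' substrate), `x` the in-image horizontal axis, and `z` the slice index
#' (milling direction). `spacing_nm` gives the physical sample spacing along
#' the three array axes in that order; the z spacing is the slice thickness.
#'
#' Label semantics: 0 background, 1 substrate, 2 nanopillar, 3 cell envelope,
#' 4 cytosol.
#'
#' @param labels 3D integer array `[y, x, z]`.
#' @param spacing_nm numeric length-3, spacing along `(y, x, z)` in nm.
#' @param pillar_ids optional parallel integer array carrying per-pillar ids.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing_nm, pillar_ids = NULL) {
  stopifnot(length(dim(labels)) == 3, length(spacing_nm) == 3,
            all(spacing_nm > 0))
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(NC_LABELS))
  if (length(bad) > 0)
    stop("unknown labels in volume: ", paste(bad, collapse = ", "))
  structure(list(labels = labels,
                 spacing_nm = as.numeric(spacing_nm),
                 pillar_ids = pillar_ids),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g nm\n",
              d[1], d[2], d[3], x$spacing_nm[1], x$spacing_nm[2], x$spacing_nm[3]))
  tab <- table(factor(x$labels, levels = NC_LABELS, labels = names(NC_LABELS)))
  print(tab)
  invisible(x)
}

#' Grayscale image stack
#'
#' A slice-and-view image stack: `intensities` is a 3D array `[y, x, slice]`
#' of 8-bit grayscale values (0-255). Acquisition metadata records the stage
#' tilt, slice thickness and pixel size, plus flags saying whether the stack
#' has been drift-aligned and foreshortening-corrected.
#'
#' @param intensities 3D numeric array `[y, x, slice]`, values in 0-255.
#' @param pixel_size_nm in-image pixel size (nm).
#' @param slice_thickness_nm physical slice thickness (nm).
#' @param tilt_deg stage tilt in degrees (the milled face is viewed at this
#'   tilt, compressing the in-image vertical axis by `sin(tilt)`).
#' @param aligned,foreshortening_corrected state flags.
#' @param canvas_margin_px width of the padding frame added around the
#'   imaged region (simulated stacks enlarge the canvas so drifting content
#'   stays in view); [crop_canvas()] removes it after alignment.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(intensities, pixel_size_nm, slice_thickness_nm,
                        tilt_deg = 52, aligned = FALSE,
                        foreshortening_corrected = FALSE,
                        canvas_margin_px = 0) {
  stopifnot(length(dim(intensities)) == 3,
            pixel_size_nm > 0, slice_thickness_nm > 0,
            tilt_deg > 0, tilt_deg <= 90, canvas_margin_px >= 0)
  structure(list(intensities = intensities,
                 pixel_size_nm = pixel_size_nm,
                 slice_thickness_nm = slice_thickness_nm,
                 tilt_deg = tilt_deg,
                 aligned = aligned,
                 foreshortening_corrected = foreshortening_corrected,
                 canvas_margin_px = canvas_margin_px),
            class = "image_stack")
}

#' Remove the drift-accommodation margin from an aligned stack
#'
#' After alignment the content returns to its original placement inside the
#' enlarged canvas; cropping the margin restores the original field of view
#' so coordinates match the source volume.
#'
#' @param stack an aligned [image_stack()].
#' @return the cropped [image_stack()].
#' @export
crop_canvas <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  m <- stack$canvas_margin_px
  if (m == 0) return(stack)
  if (!stack$aligned)
    stop("crop the canvas only after alignment")
  d <- dim(stack$intensities)
  stack$intensities <- stack$intensities[(m + 1):(d[1] - m),
                                         (m + 1):(d[2] - m), , drop = FALSE]
  stack$canvas_margin_px <- 0
  stack
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(paste0("<image_stack> %d slices of %d x %d px, pixel %.3g nm, ",
                     "slice %.3g nm, tilt %.3g deg\n  aligned: %s, ",
                     "foreshortening corrected: %s\n"),
              d[3], d[1], d[2], x$pixel_size_nm, x$slice_thickness_nm,
              x$tilt_deg, x$aligned, x$foreshortening_corrected))
  invisible(x)
}

n_slices <- function(stack) dim(stack$intensities)[3]

#' Write / read an image stack as multipage TIFF with a JSON sidecar
#'
#' One 8-bit grayscale page per slice; acquisition metadata travels in a
#' `<path>.json` sidecar. Reading a stack without a sidecar applies defaults
#' (pixel 10 nm, slice 30 nm, tilt 52 degrees) with a warning.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(n_slices(stack)), function(k)
    pmin(pmax(stack$intensities[, , k], 0), 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(pixel_size_nm = stack$pixel_size_nm,
               slice_thickness_nm = stack$slice_thickness_nm,
               tilt_deg = stack$tilt_deg,
               aligned = stack$aligned,
               foreshortening_corrected = stack$foreshortening_corrected,
               canvas_margin_px = stack$canvas_margin_px)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path))
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged page sizes in ", path)
  arr <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]  # tolerate grey stored as RGB
    arr[, , k] <- round(pg * 255)
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    warning("no metadata sidecar for ", path, "; applying defaults")
    meta <- list(pixel_size_nm = 10, slice_thickness_nm = 30, tilt_deg = 52,
                 aligned = FALSE, foreshortening_corrected = FALSE)
  }
  image_stack(arr,
              pixel_size_nm = meta$pixel_size_nm,
              slice_thickness_nm = meta$slice_thickness_nm,
              tilt_deg = meta$tilt_deg,
              aligned = isTRUE(meta$aligned),
              foreshortening_corrected = isTRUE(meta$foreshortening_corrected),
              canvas_margin_px = meta$canvas_margin_px %||% 0)
}

#' Write / read a label volume as multipage 16-bit TIFF plus JSON sidecar
#'
#' @param volume a [label_volume()].
#' @param path TIFF file path.
#' @return `write_label_volume` returns `path` invisibly; `read_label_volume`
#'   returns a [label_volume()].
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  pages <- lapply(seq_len(dim(volume$labels)[3]), function(k)
    volume$labels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(spacing_nm = volume$spacing_nm,
               labels = as.list(NC_LABELS))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(round(pages[[k]] * 65535))
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("label volume sidecar missing: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  label_volume(arr, spacing_nm = meta$spacing_nm)
}
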