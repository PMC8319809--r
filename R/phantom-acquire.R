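#' Acquisition parameters for simulated slice-and-view imaging
#'
#' Models the distortions of FIB-SEM slice-and-view acquisition: the milled
#' face is viewed at the stage tilt (compressing the in-image vertical axis
#' by `sin(tilt)`), consecutive slices drift by a random walk, and images
#' carry Gaussian noise and optional vertical curtaining stripes.
#'
#' @param tilt_deg stage tilt, degrees in (0, 90]; 52 by convention.
#' @param slice_thickness_nm milling step: 30 nm for rod (E. coli) scenes,
#'   20 nm for coccus (S. aureus) scenes.
#' @param pixel_size_nm in-image pixel size.
#' @param drift_sd_px per-slice random-walk drift step sd (pixels).
#' @param noise_sd additive Gaussian noise sd on the 8-bit scale (redrawn
#'   per image: not content-locked).
#' @param texture_sd sd of a smooth volumetric material texture added to the
#'   gray levels (8-bit units). Unlike `noise_sd`, texture is locked to the
#'   scene content, so it drifts with the slices - the graininess that makes
#'   real milled faces registrable.
#' @param curtaining_amplitude amplitude of vertical stripe artifacts
#'   (8-bit units); 0 disables.
#' @param gray_lookup named vector mapping labels to gray levels.
#' @return an object of class `acquisition_params`.
#' @export
acquisition_params <- function(tilt_deg = 52, slice_thickness_nm = 30,
                               pixel_size_nm = 10, drift_sd_px = 0,
                               noise_sd = 0, texture_sd = 0,
                               curtaining_amplitude = 0,
                               gray_lookup = NC_GRAY) {
  stopifnot(tilt_deg > 0, tilt_deg <= 90, slice_thickness_nm > 0,
            pixel_size_nm > 0, drift_sd_px >= 0, noise_sd >= 0,
            texture_sd >= 0, curtaining_amplitude >= 0,
            all(names(NC_GRAY) %in% names(gray_lookup)))
  structure(list(tilt_deg = tilt_deg,
                 slice_thickness_nm = slice_thickness_nm,
                 pixel_size_nm = pixel_size_nm,
                 drift_sd_px = drift_sd_px,
                 noise_sd = noise_sd,
                 texture_sd = texture_sd,
                 curtaining_amplitude = curtaining_amplitude,
                 gray_lookup = gray_lookup),
            class = "acquisition_params")
}

# linear resize of the row (y) axis of a [y, x] matrix to n2 rows, mapping
# row coordinate y2 (0-based) to y2 * (scale) in the source
resize_rows <- function(m, n2, scale) {
  n1 <- nrow(m)
  y <- (seq_len(n2) - 1) * scale
  lo <- pmin(floor(y), n1 - 1)
  hi <- pmin(lo + 1, n1 - 1)
  f <- y - lo
  m[lo + 1, , drop = FALSE] * (1 - f) + m[hi + 1, , drop = FALSE] * f
}

# integer translation: content moves by (+dy, +dx); vacated area filled
translate_slice <- function(m, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  ys <- seq_len(nrow(m)) - dy
  xs <- seq_len(ncol(m)) - dx
  oky <- ys >= 1 & ys <= nrow(m)
  okx <- xs >= 1 & xs <= ncol(m)
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Simulate FIB-SEM acquisition of a phantom volume
#'
#' Maps labels to grayscale, compresses the in-image vertical axis by
#' `sin(tilt)` (stage-tilt foreshortening), applies a seeded integer-pixel
#' random-walk drift across slices, and adds Gaussian noise and optional
#' curtaining stripes. The injected per-slice cumulative offsets are
#' returned, and recorded in the ground truth when one is supplied.
#'
#' @param volume a [label_volume()]; its z spacing becomes the slice
#'   thickness and its y/x spacing must match `acq$pixel_size_nm`.
#' @param acq an [acquisition_params()].
#' @param seed integer seed for drift and noise.
#' @param ground_truth optional phantom ground truth to record offsets in.
#' @return list with `stack` (an [image_stack()]), `offsets` (n_slices x 2
#'   matrix of cumulative `(dy, dx)` pixel offsets) and `ground_truth`
#'   (augmented copy, or `NULL`).
#' @export
simulate_acquisition <- function(volume, acq, seed = 1, ground_truth = NULL) {
  stopifnot(inherits(volume, "label_volume"),
            inherits(acq, "acquisition_params"))
  set.seed(seed)
  lut <- numeric(max(NC_LABELS) + 1)
  lut[NC_LABELS + 1] <- acq$gray_lookup[names(NC_LABELS)]
  gray <- array(lut[volume$labels + 1], dim(volume$labels))
  if (acq$texture_sd > 0) {
    tex <- array(rnorm(length(gray)), dim(gray))
    tex <- .sepconv3(tex, c(1, 4, 6, 4, 1) / 16)
    gray <- gray + tex * (acq$texture_sd / sd(tex))
  }

  s <- sin(acq$tilt_deg * pi / 180)
  d <- dim(gray)
  ny2 <- max(round(d[1] * s), 2)
  nsl <- d[3]

  # per-slice cumulative integer drift (random walk, first slice at origin)
  if (acq$drift_sd_px > 0) {
    steps_y <- rnorm(nsl - 1, 0, acq$drift_sd_px)
    steps_x <- rnorm(nsl - 1, 0, acq$drift_sd_px)
    offsets <- cbind(dy = c(0L, as.integer(round(cumsum(steps_y)))),
                     dx = c(0L, as.integer(round(cumsum(steps_x)))))
  } else {
    offsets <- cbind(dy = integer(nsl), dx = integer(nsl))
  }

  # enlarge the canvas so drifting content stays in view (as an operator
  # framing the ROI would), rather than sliding off the detector edge
  margin <- if (any(offsets != 0)) max(abs(offsets)) + 4L else 0L
  bg <- acq$gray_lookup[["background"]]
  nyc <- ny2 + 2L * margin
  nxc <- d[2] + 2L * margin

  curtain <- if (acq$curtaining_amplitude > 0) {
    raw <- rnorm(nxc)
    ker <- exp(-0.5 * ((-5:5) / 2)^2)
    smooth <- as.numeric(stats::filter(c(rep(raw[1], 5), raw, rep(raw[nxc], 5)),
                                       ker / sum(ker), sides = 2))[6:(nxc + 5)]
    acq$curtaining_amplitude * smooth / max(abs(smooth))
  } else NULL

  out <- array(0, c(nyc, nxc, nsl))
  for (k in seq_len(nsl)) {
    sl <- matrix(bg, nyc, nxc)
    sl[margin + seq_len(ny2), margin + seq_len(d[2])] <-
      resize_rows(gray[, , k], ny2, 1 / s)
    if (any(offsets[k, ] != 0))
      sl <- translate_slice(sl, offsets[k, 1], offsets[k, 2], fill = bg)
    if (!is.null(curtain))
      sl <- sl + matrix(curtain, nyc, nxc, byrow = TRUE)
    if (acq$noise_sd > 0)
      sl <- sl + matrix(rnorm(length(sl), 0, acq$noise_sd), nyc, nxc)
    out[, , k] <- pmin(pmax(sl, 0), 255)
  }

  stack <- image_stack(out,
                       pixel_size_nm = volume$spacing_nm[2],
                       slice_thickness_nm = volume$spacing_nm[3],
                       tilt_deg = acq$tilt_deg,
                       canvas_margin_px = margin)
  if (!is.null(ground_truth)) ground_truth$slice_offsets <- offsets
  list(stack = stack, offsets = offsets, ground_truth = ground_truth)
}
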