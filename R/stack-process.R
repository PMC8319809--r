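#' Align a slice stack by translation-only cross-correlation
#'
#' Each slice is registered to its predecessor with an integer-pixel
#' translation maximizing the normalized cross-correlation (computed via
#' FFT); pairwise shifts are accumulated from slice 0 and undone, with
#' out-of-canvas regions zero-padded. Ties in the correlation peak are
#' broken by the smallest displacement magnitude, then lexicographically by
#' `(dy, dx)`. All-constant slices cannot be registered: they get zero
#' offset and a zero confidence flag rather than an error.
#'
#' @param stack an [image_stack()].
#' @param max_shift_px search radius for the per-pair shift.
#' @return list with `stack` (aligned, flag set) and `alignment`: per-slice
#'   cumulative `offsets` (n x 2, `(dy, dx)`) and per-pair `confidence`
#'   in \[0, 1\].
#' @export
align_stack <- function(stack, max_shift_px = 30) {
  stopifnot(inherits(stack, "image_stack"))
  n <- n_slices(stack)
  if (n < 2) stop("alignment needs at least 2 slices")
  if (stack$aligned) {
    return(list(stack = stack,
                alignment = list(offsets = matrix(0, n, 2,
                                                  dimnames = list(NULL, c("dy", "dx"))),
                                 confidence = rep(1, n - 1))))
  }
  offsets <- matrix(0L, n, 2, dimnames = list(NULL, c("dy", "dx")))
  confidence <- numeric(n - 1)
  for (k in 2:n) {
    est <- register_pair(stack$intensities[, , k - 1],
                         stack$intensities[, , k], max_shift_px)
    offsets[k, ] <- offsets[k - 1, ] + est$shift
    confidence[k - 1] <- est$confidence
  }
  out <- stack$intensities
  for (k in 2:n) {
    if (any(offsets[k, ] != 0))
      out[, , k] <- translate_slice(out[, , k], -offsets[k, 1], -offsets[k, 2])
  }
  stack$intensities <- out
  stack$aligned <- TRUE
  list(stack = stack,
       alignment = list(offsets = offsets, confidence = confidence))
}

# integer shift (dy, dx) such that b approx equals a translated by (dy, dx),
# by FFT cross-correlation of mean-subtracted images
register_pair <- function(a, b, max_shift_px) {
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  na <- sqrt(sum(a0^2)); nb <- sqrt(sum(b0^2))
  if (na == 0 || nb == 0)
    return(list(shift = c(0L, 0L), confidence = 0))
  cc <- Re(fft(fft(b0) * Conj(fft(a0)), inverse = TRUE)) / length(a0)
  ny <- nrow(a); nx <- ncol(a)
  sy <- c(0:(ny - 1)); sy[sy > ny / 2] <- sy[sy > ny / 2] - ny
  sx <- c(0:(nx - 1)); sx[sx > nx / 2] <- sx[sx > nx / 2] - nx
  oky <- abs(sy) <= max_shift_px
  okx <- abs(sx) <= max_shift_px
  win <- cc[oky, okx, drop = FALSE]
  wy <- sy[oky]; wx <- sx[okx]
  peak <- max(win)
  cand <- which(win >= peak - 1e-9 * abs(peak), arr.ind = TRUE)
  dy <- wy[cand[, 1]]; dx <- wx[cand[, 2]]
  ord <- order(dy^2 + dx^2, dy, dx)
  best <- ord[1]
  list(shift = c(dy[best], dx[best]),
       confidence = max(min(peak * length(a0) / (na * nb), 1), 0))
}

#' Correct stage-tilt foreshortening
#'
#' Viewing the milled cross section at stage tilt `t` compresses the
#' in-image vertical axis by `sin(t)`; this rescales it by `1/sin(t)` with
#' linear interpolation and sets the corrected flag (double correction is a
#' state error).
#'
#' @param stack an [image_stack()].
#' @return the corrected [image_stack()].
#' @export
correct_foreshortening <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$foreshortening_corrected)
    stop("stack is already foreshortening-corrected")
  if (stack$tilt_deg <= 0 || stack$tilt_deg > 90)
    stop("tilt_deg must be in (0, 90]")
  s <- sin(stack$tilt_deg * pi / 180)
  d <- dim(stack$intensities)
  ny2 <- max(round(d[1] / s), 2)
  if (ny2 != d[1]) {
    out <- array(0, c(ny2, d[2], d[3]))
    for (k in seq_len(d[3]))
      out[, , k] <- resize_rows(stack$intensities[, , k], ny2, s)
    stack$intensities <- out
  }
  stack$foreshortening_corrected <- TRUE
  stack
}

#' Segment an aligned, corrected stack into a label volume
#'
#' Maps intensity bands to labels with fixed grayscale cuts or multi-level
#' Otsu thresholding, after optional 3x3x3 median denoising. Morphological
#' cleanup removes per-label connected components below a minimum voxel
#' count (orphaned voxels are re-assigned to the local majority label) and
#' fills enclosed background holes inside each label.
#'
#' @param stack an [image_stack()], aligned and foreshortening-corrected.
#' @param thresholds ascending grayscale cut values (k cuts make k+1 bands),
#'   or `"auto"` for multi-level Otsu with `n_classes` classes.
#' @param band_labels label assigned to each band, ascending by intensity.
#' @param n_classes number of classes for `"auto"` thresholding.
#' @param denoise apply the median prefilter (recommended whenever the
#'   stack carries noise).
#' @param min_component_voxels cleanup size threshold.
#' @param pillar_restore_margin intensity margin above the top cut required
#'   to restore median-eroded pillar voxels inside the envelope.
#' @param check_state error when the stack is not aligned/corrected.
#' @return a [label_volume()] with y/x spacing the pixel size and z spacing
#'   the slice thickness.
#' @export
segment_labels <- function(stack, thresholds = NC_CUTS,
                           band_labels = NC_CUT_LABELS,
                           n_classes = 5, denoise = FALSE,
                           min_component_voxels = 30,
                           pillar_restore_margin = 10,
                           check_state = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  if (check_state && !(stack$aligned && stack$foreshortening_corrected))
    stop("stack must be aligned and foreshortening-corrected before segmentation")
  raw <- stack$intensities
  img <- if (denoise) .median3(raw) else raw
  if (identical(thresholds, "auto")) {
    thresholds <- multiotsu(img, n_classes)
    if (length(band_labels) != n_classes)
      band_labels <- NC_CUT_LABELS[seq_len(n_classes)]
  }
  stopifnot(length(band_labels) == length(thresholds) + 1,
            !is.unsorted(thresholds))
  lab <- array(band_labels[findInterval(img, thresholds) + 1L], dim(img))
  # vertical blend voxels exist only when the foreshortening correction
  # actually interpolated the vertical axis
  if (sin(stack$tilt_deg * pi / 180) < 1 - 1e-9)
    lab <- unmix_boundary_bands(lab, img, band_labels)
  if (denoise) {
    # The median erodes structures thinner than its window (nanopillar
    # tips), so pillar evidence from the raw thresholds is restored and the
    # component-size cleanup drops the speckles this re-admits. Where the
    # median settled on envelope, restoring on borderline intensities would
    # inflate the pillar by the envelope/pillar boundary shell, so there a
    # margin above the cut is required.
    pillar_label <- NC_LABELS[["pillar"]]
    band_of_raw <- band_labels[findInterval(raw, thresholds) + 1L]
    pillar_cut <- thresholds[which(band_labels == pillar_label) - 1]
    strong <- raw >= pillar_cut + pillar_restore_margin
    restore <- band_of_raw == pillar_label &
      (lab != NC_LABELS[["envelope"]] | strong)
    lab[array(restore, dim(raw))] <- pillar_label
    # grow along voxel-thin tip chains: raw pillar evidence directly against
    # established pillar voxels is restored even inside the envelope
    evid <- array(band_of_raw == pillar_label, dim(raw))
    for (pass in 1:3) {
      adj <- touches_label(lab, pillar_label)
      add <- evid & adj & lab != pillar_label
      if (!any(add)) break
      lab[add] <- pillar_label
    }
  }
  lab <- cleanup_labels(lab, min_component_voxels)
  label_volume(lab, c(stack$pixel_size_nm, stack$pixel_size_nm,
                      stack$slice_thickness_nm))
}

# Multi-level Otsu: dynamic programme maximizing between-class variance over
# a 256-bin histogram (equivalently minimizing within-class weighted
# variance), returning n_classes - 1 cuts.
multiotsu <- function(img, n_classes = 5) {
  h <- tabulate(pmin(pmax(floor(img), 0), 255) + 1L, 256L)
  if (sum(h > 0) < n_classes)
    stop("thresholding failure: image has fewer than ", n_classes,
         " distinct intensity levels")
  p <- h / sum(h)
  v <- 0:255
  cw <- cumsum(p)
  cm <- cumsum(p * v)
  # S[a, b]: between-class contribution mu^2 * w for bin range [a, b]
  Sfun <- function(a, b) {
    w <- cw[b] - if (a > 1) cw[a - 1] else 0
    m <- cm[b] - if (a > 1) cm[a - 1] else 0
    ifelse(w > 0, m^2 / w, 0)
  }
  k <- n_classes
  cw0 <- c(0, cw); cm0 <- c(0, cm)
  # dp[j, b] = best score splitting bins 1..b into j classes
  dp <- matrix(-Inf, k, 256)
  arg <- matrix(0L, k, 256)
  dp[1, ] <- vapply(1:256, function(b) Sfun(1, b), numeric(1))
  for (j in 2:k) {
    for (b in j:256) {
      a <- (j - 1):(b - 1)      # last bin of the previous class
      w <- cw[b] - cw0[a + 1]
      m <- cm[b] - cm0[a + 1]
      sc <- dp[j - 1, a] + ifelse(w > 0, m^2 / w, 0)
      i <- which.max(sc)
      dp[j, b] <- sc[i]
      arg[j, b] <- a[i]
    }
  }
  cuts <- integer(k - 1)
  b <- 256L
  for (j in k:2) {
    cuts[j - 1] <- arg[j, b]
    b <- arg[j, b]
  }
  # bin b covers intensity b - 1; place the cut between band edges
  as.numeric(cuts) - 0.5
}

# Foreshortening correction interpolates intensities along the in-image
# vertical axis, so a voxel on a class boundary can carry a blend of the
# classes above and below and land in an unrelated intermediate band (e.g. a
# film of "substrate" between envelope and background). A voxel is treated
# as such a blend when its label differs from both flanking labels (sampled
# two rows away, outside the blend) AND its intensity lies strictly between
# the flanking class means - i.e. it is explainable as their mixture. It is
# then re-assigned to the flank with the nearer mean, which puts the class
# boundary at the 50% blend point - unbiased. A genuine thin shell keeps its
# own class because its intensity matches no mixture of its neighbors.
unmix_boundary_bands <- function(lab, img, band_labels) {
  d <- dim(img)
  if (d[1] < 5) return(lab)
  means <- vapply(band_labels, function(L) {
    sel <- lab == L
    if (any(sel)) mean(img[sel]) else NA_real_
  }, numeric(1))
  yy <- 3:(d[1] - 2)
  lab_up <- lab[yy + 2, , , drop = FALSE]
  lab_dn <- lab[yy - 2, , , drop = FALSE]
  lab_cur <- lab[yy, , , drop = FALSE]
  mid <- img[yy, , , drop = FALSE]
  mu_up <- array(means[match(lab_up, band_labels)], dim(lab_up))
  mu_dn <- array(means[match(lab_dn, band_labels)], dim(lab_dn))
  blend <- lab_cur != lab_up & lab_cur != lab_dn &
    (mid - mu_up) * (mid - mu_dn) < 0
  blend[is.na(blend)] <- FALSE
  if (!any(blend)) return(lab)
  pick_up <- abs(mid - mu_up) <= abs(mid - mu_dn)
  new_lab <- ifelse(pick_up, lab_up, lab_dn)
  lab_cur[blend] <- new_lab[blend]
  lab[yy, , ] <- lab_cur
  lab
}

cleanup_labels <- function(lab, min_component_voxels) {
  if (min_component_voxels <= 1) return(lab)
  dims <- dim(lab)
  present <- setdiff(sort(unique(as.vector(lab))), 0L)
  orphan <- array(FALSE, dims)
  for (L in present) {
    mask <- array(as.integer(lab == L), dims)
    cc <- .cc3d(mask, 26L)
    sizes <- tabulate(cc[cc > 0])
    small <- which(sizes < min_component_voxels)
    if (length(small) > 0) {
      sel <- array(cc %in% small, dims)
      lab[sel] <- 0L
      orphan[sel] <- TRUE
    }
  }
  # re-assign orphaned voxels to the local 6-neighborhood majority
  for (pass in 1:3) {
    idx <- which(orphan)
    if (length(idx) == 0) break
    votes <- neighbor_majority(lab, idx, dims)
    settled <- votes >= 0
    lab[idx[settled]] <- votes[settled]
    orphan[idx[settled]] <- FALSE
  }
  # fill enclosed background holes per label
  for (L in present) {
    inv <- array(as.integer(lab != L), dims)
    cc <- .cc3d(inv, 6L)
    border <- unique(c(cc[1, , ], cc[dims[1], , ], cc[, 1, ], cc[, dims[2], ],
                       cc[, , 1], cc[, , dims[3]]))
    enclosed <- setdiff(setdiff(unique(as.vector(cc)), 0L), border)
    for (comp in enclosed) {
      sel <- cc == comp
      if (all(lab[sel] == 0L)) lab[sel] <- L
    }
  }
  lab
}

# majority label over the 6-neighborhood of the given linear indices;
# -1 when no labeled neighbor exists
neighbor_majority <- function(lab, idx, dims) {
  iy <- (idx - 1L) %% dims[1] + 1L
  ix <- ((idx - 1L) %/% dims[1]) %% dims[2] + 1L
  iz <- (idx - 1L) %/% (dims[1] * dims[2]) + 1L
  vals <- matrix(-1L, length(idx), 6)
  k <- 0L
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    k <- k + 1L
    jy <- iy + d[1]; jx <- ix + d[2]; jz <- iz + d[3]
    ok <- jy >= 1 & jy <= dims[1] & jx >= 1 & jx <= dims[2] &
      jz >= 1 & jz <= dims[3]
    v <- rep(-1L, length(idx))
    v[ok] <- lab[cbind(jy[ok], jx[ok], jz[ok])]
    vals[, k] <- v
  }
  apply(vals, 1, function(r) {
    r <- r[r >= 1]
    if (length(r) == 0) return(-1L)
    as.integer(names(which.max(table(r))))
  })
}
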