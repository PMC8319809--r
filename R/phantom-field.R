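#' Nanopillar field parameters
#'
#' Describes a nanostructured surface as a random pillar field: areal density,
#' truncated-normal height and tip-diameter distributions, orientation mode
#' and a hard-core minimum spacing.
#'
#' @param density_per_um2 expected number of pillars per square micron.
#' @param height_mean_nm,height_sd_nm pillar height distribution (nm);
#'   sampled heights are truncated to be positive.
#' @param tip_diameter_mean_nm,tip_diameter_sd_nm tip diameter distribution
#'   (nm), truncated positive.
#' @param orientation_mode `"aligned"` (all axes vertical) or `"random"`
#'   (axes tilted up to `max_tilt_deg` with uniform azimuth).
#' @param max_tilt_deg maximum tilt from vertical, degrees, in \[0, 45\].
#' @param field_size_um extent of the field, `c(x, z)` in microns.
#' @param min_spacing_nm hard-core minimum distance between pillar bases.
#' @param base_diameter_factor base diameter as a multiple of tip diameter
#'   (pillars are truncated cones capped by a hemispherical tip).
#' @return an object of class `pillar_field_params`.
#' @export
pillar_field_params <- function(density_per_um2,
                                height_mean_nm, height_sd_nm,
                                tip_diameter_mean_nm, tip_diameter_sd_nm,
                                orientation_mode = c("random", "aligned"),
                                max_tilt_deg = 30,
                                field_size_um = c(10, 10),
                                min_spacing_nm = 0,
                                base_diameter_factor = 2) {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(density_per_um2 >= 0,
            height_mean_nm > 0, height_sd_nm >= 0,
            tip_diameter_mean_nm > 0, tip_diameter_sd_nm >= 0,
            max_tilt_deg >= 0, max_tilt_deg <= 45,
            length(field_size_um) == 2, all(field_size_um > 0),
            min_spacing_nm >= 0, base_diameter_factor >= 1)
  structure(list(density_per_um2 = density_per_um2,
                 height_mean_nm = height_mean_nm,
                 height_sd_nm = height_sd_nm,
                 tip_diameter_mean_nm = tip_diameter_mean_nm,
                 tip_diameter_sd_nm = tip_diameter_sd_nm,
                 orientation_mode = orientation_mode,
                 max_tilt_deg = max_tilt_deg,
                 field_size_um = as.numeric(field_size_um),
                 min_spacing_nm = min_spacing_nm,
                 base_diameter_factor = base_diameter_factor),
            class = "pillar_field_params")
}

#' Surface presets
#'
#' The four characterized nanotopographies: alkaline-hydrothermal TiO2
#' pillars (`ah-ns-medium`, 444 +/- 85 nm tall, 43 +/- 9 nm tips, 36 per
#' um2), thermally oxidised short and long TiO2 pillars (`to-ns-short`,
#' 350 +/- 52 nm / 27 +/- 4 nm / 58 per um2; `to-ns-long`, 1700 +/- 347 nm /
#' 114 +/- 26 nm / 8 per um2), and plasma-etched black-silicon pillars
#' (`pe-ns-short`, 181 +/- 26 nm / 50 +/- 6 nm / 137 per um2). Only the
#' plasma-etched pillars are vertically aligned; the others grow in random
#' orientations. Minimum spacings are not reported for these surfaces and
#' are package conventions scaled to the mean pitch.
#'
#' @param name preset name (case-insensitive; `_` and `-` interchangeable).
#' @param field_size_um field extent `c(x, z)` in microns.
#' @return a [pillar_field_params()].
#' @export
surface_preset <- function(name, field_size_um = c(10, 10)) {
  key <- gsub("_", "-", tolower(name))
  presets <- list(
    "ah-ns-medium" = list(36, 444, 85, 43, 9, "random", 30, 100),
    "to-ns-short"  = list(58, 350, 52, 27, 4, "random", 30, 80),
    "to-ns-long"   = list(8, 1700, 347, 114, 26, "random", 30, 200),
    "pe-ns-short"  = list(137, 181, 26, 50, 6, "aligned", 0, 40))
  if (!key %in% names(presets))
    stop("unknown preset: ", name, " (expected one of ",
         paste(names(presets), collapse = ", "), ")")
  p <- presets[[key]]
  pillar_field_params(density_per_um2 = p[[1]],
                      height_mean_nm = p[[2]], height_sd_nm = p[[3]],
                      tip_diameter_mean_nm = p[[4]], tip_diameter_sd_nm = p[[5]],
                      orientation_mode = p[[6]], max_tilt_deg = p[[7]],
                      field_size_um = field_size_um,
                      min_spacing_nm = p[[8]])
}

rtruncnorm_pos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Sample a nanopillar field
#'
#' Draws a Poisson number of pillars with expectation density x area and
#' places them by seeded uniform rejection sampling honoring the hard-core
#' minimum spacing. Heights and tip diameters come from truncated normal
#' distributions; `aligned` fields have vertical axes, `random` fields tilt
#' each axis by a uniform angle up to `max_tilt_deg` with uniform azimuth.
#'
#' @param params a [pillar_field_params()].
#' @param seed integer seed; identical `(params, seed)` reproduce the field
#'   bit-for-bit.
#' @return a `data.frame` of pillar specs: `pillar_id`, base position
#'   (`base_x_nm`, `base_z_nm`), unit axis (`axis_x`, `axis_y`, `axis_z`),
#'   `height_nm`, `tip_diameter_nm`, `base_diameter_nm`.
#' @export
sample_pillar_field <- function(params, seed = 1) {
  stopifnot(inherits(params, "pillar_field_params"))
  set.seed(seed)
  fx <- params$field_size_um[1] * 1000
  fz <- params$field_size_um[2] * 1000
  area_um2 <- prod(params$field_size_um)
  n <- rpois(1, params$density_per_um2 * area_um2)
  empty <- data.frame(pillar_id = integer(0), base_x_nm = numeric(0),
                      base_z_nm = numeric(0), axis_x = numeric(0),
                      axis_y = numeric(0), axis_z = numeric(0),
                      height_nm = numeric(0), tip_diameter_nm = numeric(0),
                      base_diameter_nm = numeric(0))
  if (n == 0) return(empty)

  smin <- params$min_spacing_nm
  xs <- numeric(n); zs <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 100L * n
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    px <- runif(1, 0, fx); pz <- runif(1, 0, fz)
    if (placed > 0 && smin > 0) {
      d2 <- (xs[seq_len(placed)] - px)^2 + (zs[seq_len(placed)] - pz)^2
      if (min(d2) < smin^2) next
    }
    placed <- placed + 1L
    xs[placed] <- px; zs[placed] <- pz
  }
  if (placed < n)
    stop(sprintf(paste0("pillar placement failed: %d of %d placed after %d ",
                        "attempts; density %.3g per um2 is unsatisfiable at ",
                        "min spacing %.3g nm"),
                 placed, n, attempts, params$density_per_um2, smin))

  heights <- rtruncnorm_pos(n, params$height_mean_nm, params$height_sd_nm)
  tips <- rtruncnorm_pos(n, params$tip_diameter_mean_nm,
                         params$tip_diameter_sd_nm)
  if (params$orientation_mode == "aligned" || params$max_tilt_deg == 0) {
    ax <- rep(0, n); ay <- rep(1, n); az <- rep(0, n)
  } else {
    theta <- runif(n, 0, params$max_tilt_deg) * pi / 180
    phi <- runif(n, 0, 2 * pi)
    ax <- sin(theta) * cos(phi)
    ay <- cos(theta)
    az <- sin(theta) * sin(phi)
  }
  data.frame(pillar_id = seq_len(n),
             base_x_nm = xs, base_z_nm = zs,
             axis_x = ax, axis_y = ay, axis_z = az,
             height_nm = heights,
             tip_diameter_nm = tips,
             base_diameter_nm = params$base_diameter_factor * tips)
}
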