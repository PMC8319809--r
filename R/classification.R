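#' Classification thresholds
#'
#' The interaction definitions are qualitative (indentation, piercing,
#' turgor loss, lateral pinning); these thresholds operationalize them.
#' `tau_deform_nm` defaults to 15 nm, about one slice thickness: below
#' measurement resolution nothing is called deformation. Rupture is a
#' per-cell condition: a penetrated cell whose volume deficit reaches
#' `tau_rupture_volume_fraction` is called ruptured. Sidewall contacts at or
#' above `impedance_height_fraction` of the cell height count as impedance.
#'
#' @param tau_deform_nm minimum deformation depth (nm).
#' @param tau_rupture_volume_fraction minimum cell volume deficit.
#' @param impedance_height_fraction minimum contact height on the cell.
#' @param epsilon_nm contact distance the geometries were measured with.
#' @return an object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(tau_deform_nm = 15,
                                      tau_rupture_volume_fraction = 0.20,
                                      impedance_height_fraction = 0.25,
                                      epsilon_nm = 30) {
  stopifnot(tau_deform_nm > 0,
            tau_rupture_volume_fraction > 0, tau_rupture_volume_fraction < 1,
            impedance_height_fraction > 0, impedance_height_fraction < 1,
            epsilon_nm > 0)
  structure(list(tau_deform_nm = tau_deform_nm,
                 tau_rupture_volume_fraction = tau_rupture_volume_fraction,
                 impedance_height_fraction = impedance_height_fraction,
                 epsilon_nm = epsilon_nm),
            class = "classification_thresholds")
}

#' Cell volume deficit
#'
#' Fraction of the reference volume lost: `max(0, 1 - cell / reference)`.
#' Growth beyond the reference is not a deficit (clamped to 0).
#'
#' @param cell_volume_um3 measured cell volume.
#' @param reference_volume_um3 reference (undeformed) volume; must be > 0.
#' @return deficit fraction in \[0, 1\].
#' @export
assess_volume_deficit <- function(cell_volume_um3, reference_volume_um3) {
  if (reference_volume_um3 <= 0)
    stop("reference volume must be positive")
  max(0, 1 - cell_volume_um3 / reference_volume_um3)
}

#' Classify one pillar-cell contact
#'
#' Explicit decision ladder, first match wins:
#' 1. penetration depth > 0 and cell volume deficit at/above the rupture
#'    threshold: `rupture`;
#' 2. penetration depth > 0: `penetration`;
#' 3. deformation depth at/above `tau_deform_nm`: `deformation`;
#' 4. positive contact area on the sidewall at/above the impedance height,
#'    with sub-threshold deformation: `impedance`;
#' 5. positive contact area: `none` (contact without morphological effect).
#' No contact returns `NULL` (no record).
#'
#' @param geom a `contact_geometry` from [tip_contact_area()], with
#'   `penetration_depth_nm` and `deformation_depth_nm` filled in.
#' @param cell_volume_deficit from [assess_volume_deficit()].
#' @param thresholds a [classification_thresholds()].
#' @return a one-row `data.frame` (`contact_record`), or `NULL`.
#' @export
classify_contact <- function(geom, cell_volume_deficit = 0,
                             thresholds = classification_thresholds()) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  pen <- geom$penetration_depth_nm %||% 0
  def <- geom$deformation_depth_nm %||% 0
  area <- geom$tip_contact_area_nm2 %||% 0
  if ((pen > 0 || def > 0) && area <= 0)
    stop("inconsistent contact geometry: positive depth ",
         "with zero contact area")
  if (pen > 0 && def > 0)
    stop("inconsistent contact geometry: penetration and deformation ",
         "depths are mutually exclusive")
  cls <- if (pen > 0 && cell_volume_deficit >= thresholds$tau_rupture_volume_fraction)
    "rupture"
  else if (pen > 0) "penetration"
  else if (def >= thresholds$tau_deform_nm) "deformation"
  else if (area > 0 &&
             identical(geom$contact_zone, "sidewall") &&
             isTRUE((geom$contact_height_fraction %||% 0) >=
                      thresholds$impedance_height_fraction))
    "impedance"
  else if (area > 0) "none"
  else return(NULL)
  rec <- data.frame(pillar_id = geom$pillar_id %||% NA_integer_,
                    interaction_class = cls,
                    penetration_depth_nm = pen,
                    deformation_depth_nm = def,
                    tip_contact_area_nm2 = area,
                    contact_zone = geom$contact_zone %||% NA_character_,
                    contact_height_fraction =
                      geom$contact_height_fraction %||% NA_real_,
                    stringsAsFactors = FALSE)
  class(rec) <- c("contact_record", "data.frame")
  rec
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
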