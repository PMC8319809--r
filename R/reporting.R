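#' Build a per-cell morphometric report
#'
#' Aggregates one cell's contact records into the standard report row:
#' envelope surface area, cell volume, counts and percentages of
#' penetrating / deforming / impeding nanostructures, class-wise mean
#' depths, total contacts, total nanopillar tip contact area, and the
#' contact surface area as a percentage of the envelope area. Machine
#' fields are raw floats; [format_cell_report()] renders the table view
#' (percentages and depth means truncated to 2 decimals, with the
#' averaged-values marker on depth means over several contacts).
#'
#' @param cell_id identifier for the cell.
#' @param envelope_surface_area_um2 envelope surface area (um^2).
#' @param cell_volume_um3 cell volume (um^3).
#' @param records `data.frame` of contact records ([classify_contact()])
#'   belonging to this cell; zero rows is a valid (empty) report.
#' @return an object of class `cell_report`.
#' @export
build_cell_report <- function(cell_id, envelope_surface_area_um2,
                              cell_volume_um3, records) {
  if (is.null(records))
    records <- data.frame(pillar_id = integer(0), interaction_class = character(0),
                          penetration_depth_nm = numeric(0),
                          deformation_depth_nm = numeric(0),
                          tip_contact_area_nm2 = numeric(0))
  total <- nrow(records)
  cls <- records$interaction_class
  n_pen <- sum(cls %in% c("penetration", "rupture"))
  n_def <- sum(cls == "deformation")
  n_imp <- sum(cls == "impedance")
  n_none <- sum(cls == "none")
  pct <- function(n) if (total > 0) 100 * n / total else NA_real_
  mean_or_na <- function(x) if (length(x) > 0) mean(x) else NA_real_
  rep <- list(
    cell_id = cell_id,
    envelope_surface_area_um2 = envelope_surface_area_um2,
    cell_volume_um3 = cell_volume_um3,
    n_penetrating = n_pen, pct_penetrating = pct(n_pen),
    mean_penetration_depth_nm =
      mean_or_na(records$penetration_depth_nm[cls %in% c("penetration", "rupture")]),
    n_deforming = n_def, pct_deforming = pct(n_def),
    mean_deformation_depth_nm =
      mean_or_na(records$deformation_depth_nm[cls == "deformation"]),
    n_impeding = n_imp, pct_impeding = pct(n_imp),
    n_none = n_none,
    total_contacts = total,
    total_tip_contact_area_nm2 = sum(records$tip_contact_area_nm2),
    contact_surface_area_pct =
      if (isTRUE(envelope_surface_area_um2 > 0))
        100 * sum(records$tip_contact_area_nm2) / (envelope_surface_area_um2 * 1e6)
      else NA_real_,
    records = records)
  class(rep) <- "cell_report"
  rep
}

# truncate (not round) to 2 decimals, the table convention
trunc2 <- function(x) {
  if (is.na(x)) return(NA_character_)
  sprintf("%.2f", trunc(x * 100) / 100)
}

#' Formatted (table-style) view of a cell report
#'
#' Percentages and depth means are truncated to two decimals; depth means
#' averaged over several contacts carry a trailing `*` marker. Prose-style
#' integer percentages (e.g. "92% did not penetrate") round instead - use
#' `round(100 * n / total)` on the raw fields for those.
#'
#' @param report a [build_cell_report()] result.
#' @return named character vector of rendered fields.
#' @export
format_cell_report <- function(report) {
  stopifnot(inherits(report, "cell_report"))
  star <- function(val, n) {
    if (is.na(val)) return("-")
    paste0(trunc2(val), if (n > 1) "*" else "")
  }
  c(cell_id = as.character(report$cell_id),
    envelope_surface_area_um2 = sprintf("%.1f", report$envelope_surface_area_um2),
    cell_volume_um3 = sprintf("%.2f", report$cell_volume_um3),
    n_penetrating = as.character(report$n_penetrating),
    pct_penetrating = trunc2(report$pct_penetrating) %||% "-",
    mean_penetration_depth_nm = star(report$mean_penetration_depth_nm,
                                     report$n_penetrating),
    n_deforming = as.character(report$n_deforming),
    pct_deforming = trunc2(report$pct_deforming) %||% "-",
    mean_deformation_depth_nm = star(report$mean_deformation_depth_nm,
                                     report$n_deforming),
    n_impeding = as.character(report$n_impeding),
    pct_impeding = trunc2(report$pct_impeding) %||% "-",
    total_contacts = as.character(report$total_contacts),
    total_tip_contact_area_nm2 = sprintf("%.0f", report$total_tip_contact_area_nm2),
    contact_surface_area_pct = trunc2(report$contact_surface_area_pct) %||% "-")
}

#' @export
print.cell_report <- function(x, ...) {
  cat("<cell_report>\n")
  f <- format_cell_report(x)
  for (nm in names(f)) cat(sprintf("  %-28s %s\n", nm, f[[nm]]))
  invisible(x)
}

report_fields <- c("cell_id", "envelope_surface_area_um2", "cell_volume_um3",
                   "n_penetrating", "pct_penetrating",
                   "mean_penetration_depth_nm",
                   "n_deforming", "pct_deforming", "mean_deformation_depth_nm",
                   "n_impeding", "pct_impeding", "n_none", "total_contacts",
                   "total_tip_contact_area_nm2", "contact_surface_area_pct")

#' Export cell reports
#'
#' CSV column order is fixed, mirroring the report table left to right
#' (surface area, volume, penetrating count/%, penetration depth, deforming
#' count/%, deformation depth, impeding count/%, total contacts, tip
#' contact area, contact surface area %). JSON carries raw and formatted
#' values plus the full contact record list.
#'
#' @param reports list of [build_cell_report()] results (possibly empty).
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_reports <- function(reports, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(reports, "cell_report")) reports <- list(reports)
  if (format == "csv") {
    rows <- lapply(reports, function(r) {
      vals <- lapply(report_fields, function(f) r[[f]] %||% NA)
      names(vals) <- report_fields
      as.data.frame(vals, stringsAsFactors = FALSE)
    })
    df <- if (length(rows) > 0) do.call(rbind, rows) else
      as.data.frame(stats::setNames(rep(list(logical(0)), length(report_fields)),
                                    report_fields))
    write.csv(df, path, row.names = FALSE)
  } else {
    payload <- lapply(reports, function(r) {
      raw <- r[report_fields]
      list(raw = raw, formatted = as.list(format_cell_report(r)),
           records = r$records)
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(path)
}

#' Read back cell reports exported as JSON
#'
#' @param path JSON file from [export_reports()].
#' @return list of [build_cell_report()] results.
#' @export
read_reports <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    recs <- if (length(p$records) > 0)
      do.call(rbind, lapply(p$records, function(r)
        as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                      stringsAsFactors = FALSE)))
    else NULL
    build_cell_report(p$raw$cell_id,
                      p$raw$envelope_surface_area_um2,
                      p$raw$cell_volume_um3, recs)
  })
}
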