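# CTDI conversion-factor calibration: the ratio of a measured chamber dose
# to the simulated chamber dose for the same phantom and protocol converts
# Monte Carlo output to absolute dose.  No metrology is modelled; the
# "measured" value comes from user config or the packaged synthetic fixture.

#' Packaged synthetic chamber measurement (cGy per 100 mAs axial rotation)
#'
#' Stand-in for a TG-61 style chamber reading at the centre of the 16 cm
#' CTDI phantom for a single 120 kV, 100 mAs axial rotation.  The value is
#' synthetic (no physical measurement exists in this artifact); its order of
#' magnitude matches published 120 kVp CTDI100 centre values.
#' @export
ctdi_reference_measurement <- function() 1.40

protocol_id <- function(protocol) {
  paste(protocol$mode, protocol$kvp, "kV", protocol$collimation[1], "x",
        protocol$collimation[2], "mm",
        if (protocol$mode == "helical") paste0("pitch", protocol$pitch)
        else "", sep = "_")
}

#' Derive a Monte Carlo to absolute-dose conversion factor
#'
#' factor = measured / (simulated x mAs).  The record stores the protocol
#' identity so a factor is never silently applied across protocols.
#'
#' @param measured chamber dose in cGy for the calibration scan
#' @param simulated simulated chamber dose for the same scan, in the
#'   engine's scan-scaled units per mAs (mean dose over the chamber mask of
#'   [energy_to_dose()] output at `scale = "scan"`)
#' @param protocol the [scan_protocol()] the calibration scan used
#' @return object of class `calibration_record`
#' @export
calibrate <- function(measured, simulated, protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (!is.finite(measured) || measured <= 0) stop("measured dose must be > 0")
  if (!is.finite(simulated) || simulated <= 0)
    stop("simulated dose must be > 0")
  structure(list(protocol_id = protocol_id(protocol),
                 measured_cgy = measured, simulated = simulated,
                 factor = measured / (simulated * protocol$mas),
                 date = format(Sys.Date())),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("<calibration_record> %s: factor %.6g cGy per unit per mAs\n",
              x$protocol_id, x$factor))
  invisible(x)
}

#' Convert a simulated dose grid to absolute dose (cGy)
#'
#' absolute dose = scan-scaled dose x factor x mAs; linear in mAs.
#'
#' @param dose a `dose_grid` in `keV/g` at scan scale (see
#'   [energy_to_dose()])
#' @param record a [calibrate()] record
#' @param protocol the protocol of this scan; must match the record's
#'   protocol unless `override = TRUE`
#' @param override allow cross-protocol application
#' @return a `dose_grid` with unit `cGy`
#' @export
to_absolute <- function(dose, record, protocol, override = FALSE) {
  stopifnot(inherits(dose, "dose_grid"),
            inherits(record, "calibration_record"),
            inherits(protocol, "scan_protocol"))
  if (dose$unit != "keV/g" || identical(dose$scale, "per_history"))
    stop("dose grid must be scan-scaled keV/g (energy_to_dose, scale='scan')")
  if (!identical(record$protocol_id, protocol_id(protocol)) && !override)
    stop("calibration record is for protocol '", record$protocol_id,
         "', not '", protocol_id(protocol), "' (use override = TRUE)")
  k <- record$factor * protocol$mas
  dose$values <- dose$values * k
  dose$batch <- dose$batch * k
  dose$unit <- "cGy"
  dose
}

#' Write / read calibration records as JSON
#' @param record a `calibration_record`
#' @param path file path
#' @export
write_calibration <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "calibration_record")
}
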