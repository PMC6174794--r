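# Hounsfield-unit calibration: piecewise-linear density, piecewise-constant
# material assignment.

#' CT number to density/material calibration table
#'
#' Breakpoints map Hounsfield units to mass density (linear interpolation
#' between breakpoints, clamped beyond the extremes) and to a material id
#' (piecewise constant: a voxel takes the material of the last breakpoint at
#' or below its HU).  The default four-material table is anchored at air
#' (-1000 HU, 0.00120 g/cm3) and water (0 HU, 1.000 g/cm3); scanner-specific
#' curves can be supplied instead.
#'
#' @param hu numeric vector of breakpoint HU values, strictly increasing
#' @param density mass densities (g/cm3) at the breakpoints, all > 0 except
#'   that the air anchor may be near zero
#' @param material material name per breakpoint (must exist in the
#'   cross-section library)
#' @return object of class `material_table`
#' @export
#' @examples
#' material_table()  # default air/lung/soft-tissue/bone calibration
material_table <- function(hu = c(-1000, -850, -200, 0, 120),
                           density = c(0.00120, 0.26, 0.95, 1.000, 1.10),
                           material = c("air", "lung", "soft_tissue",
                                        "soft_tissue", "bone")) {
  stopifnot(length(hu) == length(density), length(hu) == length(material),
            length(hu) >= 2)
  if (any(diff(hu) <= 0)) stop("HU breakpoints must be strictly increasing")
  if (any(density <= 0)) stop("densities must be > 0")
  structure(list(hu = as.numeric(hu), density = as.numeric(density),
                 material = as.character(material)),
            class = "material_table")
}

#' Read a material table from a JSON or YAML config file
#'
#' @param path file with fields `hu`, `density`, `material`
#' @return a [material_table()]
#' @export
read_material_table <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML config")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  material_table(cfg$hu, cfg$density, cfg$material)
}

#' Build a voxel phantom from a Hounsfield-unit volume
#'
#' Converts a CT-like HU volume into the transport medium: per-voxel mass
#' density by piecewise-linear interpolation of the calibration table
#' (clamped at the extremes) and per-voxel material id by HU bin.
#'
#' @param hu 3D array of Hounsfield units (finite)
#' @param spacing voxel spacing (dx, dy, dz) in mm
#' @param origin physical position (mm) of the centre of voxel (1,1,1)
#' @param table a [material_table()]
#' @return a [voxel_phantom()]
#' @export
#' @examples
#' hu <- array(0, c(4, 4, 2))
#' ph <- build_from_hu(hu, spacing = c(1, 1, 1))
#' stopifnot(all(ph$density == 1))
build_from_hu <- function(hu, spacing, origin = c(0, 0, 0),
                          table = material_table()) {
  stopifnot(inherits(table, "material_table"))
  if (length(dim(hu)) != 3L) stop("hu must be a 3D array")
  if (anyNA(hu) || any(!is.finite(hu))) stop("HU values must be finite")
  dens <- approx(table$hu, table$density, pmin(pmax(c(hu), min(table$hu)),
                                               max(table$hu)))$y
  bin <- findInterval(c(hu), table$hu, rightmost.closed = FALSE)
  bin[bin < 1L] <- 1L
  mat <- table$material[bin]
  mat_levels <- unique(table$material)
  voxel_phantom(array(dens, dim(hu)),
                array(match(mat, mat_levels), dim(hu)),
                spacing = spacing, origin = origin, materials = mat_levels)
}
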