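# Internal phantom / dose-grid storage: NIfTI volumes plus a JSON sidecar,
# and CSV tables for per-organ doses.  Read-only DICOM import is out of
# scope for this artifact; phantoms come from HU arrays or the synthetic
# generator.

#' Write a voxel phantom (and optional organ masks) to disk
#'
#' Stores the density and material volumes as NIfTI files, one boolean
#' NIfTI per organ mask, and a JSON sidecar with spacing, origin, material
#' names and the mask file list.
#'
#' @param phantom a [voxel_phantom()]
#' @param dir output directory (created if missing)
#' @param masks optional named list of [organ_mask()]s
#' @return the sidecar path, invisibly
#' @export
write_phantom <- function(phantom, dir, masks = NULL) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pix <- phantom$spacing
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr, pixdim = pix)
    RNifti::writeNifti(img, file.path(dir, name))
    name
  }
  wr(phantom$density, "density.nii.gz")
  wr(array(as.integer(phantom$material), dim(phantom$density)),
     "material.nii.gz")
  mask_files <- character(0)
  for (nm in names(masks))
    mask_files[nm] <- wr(array(as.integer(masks[[nm]]$mask),
                               dim(phantom$density)),
                         paste0("mask_", nm, ".nii.gz"))
  sidecar <- file.path(dir, "phantom.json")
  jsonlite::write_json(list(spacing = phantom$spacing,
                            origin = phantom$origin,
                            materials = phantom$materials,
                            dims = dim(phantom$density),
                            masks = as.list(mask_files)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a phantom written by [write_phantom()]
#' @param dir directory containing `phantom.json`
#' @return list with `phantom` and `masks`
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  rd <- function(name) {
    arr <- as.array(RNifti::readNifti(file.path(dir, name)))
    array(arr, meta$dims)
  }
  phantom <- voxel_phantom(rd("density.nii.gz"),
                           array(as.integer(rd("material.nii.gz")),
                                 meta$dims),
                           spacing = meta$spacing, origin = meta$origin,
                           materials = meta$materials)
  masks <- list()
  for (nm in names(meta$masks))
    masks[[nm]] <- organ_mask(array(rd(meta$masks[[nm]]) > 0, meta$dims),
                              nm, phantom)
  list(phantom = phantom, masks = masks)
}

#' Write a dose grid to disk (NIfTI volume + JSON sidecar)
#'
#' @param dose a `dose_grid`
#' @param dir output directory
#' @return the sidecar path, invisibly
#' @export
write_dose_grid <- function(dose, dir) {
  stopifnot(inherits(dose, "dose_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(dose$values, pixdim = dose$spacing),
                     file.path(dir, "dose.nii.gz"))
  jsonlite::write_json(
    list(unit = dose$unit, n_histories = dose$n_histories,
         n_batches = dose$n_batches, seed = dose$seed,
         total_weight = dose$total_weight, mas = dose$mas,
         tracking = dose$tracking, dims = dose$dims,
         spacing = dose$spacing, origin = dose$origin),
    file.path(dir, "dose.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "dose.json"))
}

#' Write / read per-patient organ dose tables as CSV
#'
#' Columns: patient_id, organ, protocol, dose_cgy, sigma_cgy,
#' effective_diameter_mm, age, sex (extra columns pass through).
#'
#' @param table organ-dose data.frame
#' @param path CSV path
#' @export
write_organ_doses <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_organ_doses
#' @export
read_organ_doses <- function(path) read.csv(path)
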