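# Voxel phantoms, organ masks, body contours, effective diameter, and the
# CTDI calibration phantom.
#
# Coordinate convention: voxel values refer to voxel centres; `origin` is the
# physical position (mm) of the centre of voxel (1,1,1); z is the table
# (scanner) axis.

#' Voxelized computational phantom
#'
#' @param density 3D array of mass density (g/cm3), non-negative
#' @param material 3D integer array of material indices into `materials`
#' @param spacing voxel spacing (dx, dy, dz) in mm, all > 0
#' @param origin centre of voxel (1,1,1) in mm
#' @param materials character vector naming the material indices
#' @return object of class `voxel_phantom`
#' @export
voxel_phantom <- function(density, material, spacing, origin = c(0, 0, 0),
                          materials) {
  spacing <- as.numeric(spacing)
  stopifnot(length(dim(density)) == 3L, length(spacing) == 3L,
            length(origin) == 3L)
  if (!identical(dim(density), dim(material)))
    stop("density and material grids are not congruent")
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (any(density < 0)) stop("density must be >= 0 everywhere")
  if (any(is.na(material)) || any(material < 1) ||
      any(material > length(materials)))
    stop("material indices out of range")
  structure(list(density = density, material = material, spacing = spacing,
                 origin = as.numeric(origin), materials = materials),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$density)
  cat("<voxel_phantom>", paste(d, collapse = " x "), "voxels,",
      paste(x$spacing, collapse = " x "), "mm;",
      "materials:", paste(x$materials, collapse = ", "), "\n")
  invisible(x)
}

#' Physical centre coordinates of the voxel grid along one axis
#' @param phantom a [voxel_phantom()]
#' @param axis 1, 2 or 3
#' @return numeric vector of voxel-centre coordinates (mm)
#' @export
voxel_centers <- function(phantom, axis) {
  n <- dim(phantom$density)[axis]
  phantom$origin[axis] + (seq_len(n) - 1) * phantom$spacing[axis]
}

#' Organ mask bound to a phantom
#'
#' @param mask logical 3D array congruent with the phantom
#' @param organ organ name (heart, lungs, esophagus, trachea, spinal_cord,
#'   skin, body)
#' @param phantom the phantom the mask indexes into
#' @return object of class `organ_mask`
#' @export
organ_mask <- function(mask, organ, phantom) {
  stopifnot(is.logical(mask), inherits(phantom, "voxel_phantom"))
  if (!identical(dim(mask), dim(phantom$density)))
    stop("mask not congruent with phantom")
  if (!any(mask)) stop("organ mask for '", organ, "' is empty")
  structure(list(mask = mask, organ = organ), class = "organ_mask")
}

#' Closed planar body/organ contour on one slice
#'
#' @param x,y ordered polygon vertex coordinates (mm), at least 3, forming a
#'   simple closed polygon (the closing edge is implicit)
#' @param z slice position (mm)
#' @return object of class `body_contour`
#' @export
body_contour <- function(x, y, z = 0) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("a contour needs at least 3 vertices")
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
            class = "body_contour")
}

polygon_area <- function(contour) {
  x <- contour$x; y <- contour$y
  i <- seq_along(x); j <- c(seq_along(x)[-1], 1L)
  abs(sum(x[i] * y[j] - x[j] * y[i])) / 2
}

#' Effective diameter of a body contour
#'
#' Diameter of the circle with the same cross-sectional area as the contour:
#' `2 * sqrt(A / pi)` with A from the shoelace formula.  This is the patient
#' size metric used in the dose-versus-size regressions, evaluated at a
#' reference (nipple-level) slice.
#'
#' @param contour a [body_contour()]
#' @return effective diameter in mm
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 200)[-1]
#' effective_diameter(body_contour(100 * cos(th), 100 * sin(th)))  # 200 mm
effective_diameter <- function(contour) {
  stopifnot(inherits(contour, "body_contour"))
  a <- polygon_area(contour)
  if (!is.finite(a) || a <= 0) stop("degenerate contour: non-positive area")
  2 * sqrt(a / pi)
}

# even-odd (crossing number) point-in-polygon, vectorized over points;
# half-open edge convention (vertex counted for the edge leaving it upward)
point_in_polygon <- function(px, py, vx, vy) {
  inside <- logical(length(px))
  n <- length(vx)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize per-slice contours into an organ mask
#'
#' A voxel is included iff its centre lies inside the polygon of its slice
#' (even-odd rule); slices without a polygon are empty.  Contours are matched
#' to the nearest slice within half a slice spacing.
#'
#' @param contours a [body_contour()] or list of them (one per slice)
#' @param phantom a [voxel_phantom()]
#' @param organ organ name for the resulting mask
#' @return an [organ_mask()]
#' @export
rasterize_contour <- function(contours, phantom, organ = "body") {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (inherits(contours, "body_contour")) contours <- list(contours)
  xs <- voxel_centers(phantom, 1)
  ys <- voxel_centers(phantom, 2)
  zs <- voxel_centers(phantom, 3)
  d <- dim(phantom$density)
  mask <- array(FALSE, d)
  gx <- rep(xs, times = d[2])
  gy <- rep(ys, each = d[1])
  for (ct in contours) {
    stopifnot(inherits(ct, "body_contour"))
    k <- which.min(abs(zs - ct$z))
    if (abs(zs[k] - ct$z) > phantom$spacing[3] / 2 + 1e-9) next
    mask[, , k] <- mask[, , k] |
      matrix(point_in_polygon(gx, gy, ct$x, ct$y), d[1], d[2])
  }
  if (!any(mask))
    stop("rasterization of '", organ, "' produced an empty mask ",
         "(contours outside the phantom grid?)")
  organ_mask(mask, organ, phantom)
}

#' CTDI calibration phantom with central chamber volume
#'
#' Homogeneous water cylinder aligned with the scanner (z) axis, with a
#' central cylindrical mask emulating the active volume of an ionization
#' chamber at the isocenter.  Used to derive the Monte Carlo-to-absolute-dose
#' conversion factor.
#'
#' @param diameter cylinder diameter in mm (default 160, the 16 cm head-size
#'   CTDI phantom)
#' @param length cylinder length in mm
#' @param voxel voxel size (dx, dy, dz) in mm
#' @param chamber_radius,chamber_length chamber active volume dimensions (mm);
#'   defaults approximate a 0.7 cc farmer-type thimble
#' @return list with `phantom` (a [voxel_phantom()]), `chamber` (an
#'   [organ_mask()]) and `chamber_volume_mm3` (nominal pi r^2 L)
#' @export
make_ctdi_phantom <- function(diameter = 160, length = 150,
                              voxel = c(1, 1, 3),
                              chamber_radius = 3.05, chamber_length = 24) {
  stopifnot(diameter > 0, length > 0)
  voxel <- rep(as.numeric(voxel), length.out = 3)
  if (max(voxel[1:2]) > diameter / 8)
    stop("voxel size > diameter/8: chamber volume unresolvable")
  # odd in-plane grids centre a voxel on the axis and even z grids align
  # slice boundaries with the chamber ends, so the discretized chamber volume
  # tracks the nominal cylinder closely
  nx <- ceiling((diameter + 4) / voxel[1])
  if (nx %% 2 == 0) nx <- nx + 1
  ny <- ceiling((diameter + 4) / voxel[2])
  if (ny %% 2 == 0) ny <- ny + 1
  nz <- ceiling(length / voxel[3])
  if (nz %% 2 == 1) nz <- nz + 1
  xs <- (seq_len(nx) - (nx + 1) / 2) * voxel[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * voxel[2]
  zs <- (seq_len(nz) - (nz + 1) / 2) * voxel[3]
  r2 <- outer(xs^2, ys^2, `+`)
  disc <- r2 <= (diameter / 2)^2
  density <- array(0.00120, c(nx, ny, nz))
  material <- array(1L, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    dk <- density[, , k]; mk <- material[, , k]
    dk[disc] <- 1.0; mk[disc] <- 2L
    density[, , k] <- dk; material[, , k] <- mk
  }
  ph <- voxel_phantom(density, material, spacing = voxel,
                      origin = c(xs[1], ys[1], zs[1]),
                      materials = c("air", "water"))
  ch_disc <- r2 <= chamber_radius^2
  ch_z <- abs(zs) <= chamber_length / 2
  chamber <- array(FALSE, c(nx, ny, nz))
  for (k in which(ch_z)) chamber[, , k] <- ch_disc
  list(phantom = ph,
       chamber = organ_mask(chamber, "chamber", ph),
       chamber_volume_mm3 = pi * chamber_radius^2 * chamber_length)
}
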