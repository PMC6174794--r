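# kV source model and discretized CT trajectories.
#
# Both acquisition modes are represented as ordered lists of coplanar gantry
# fields, 12 per rotation at 30 degree intervals.  Axial mode keeps one
# isocenter z per rotation and steps by the full beam width between
# rotations; helical mode advances the isocenter by pitch * W / 12 between
# consecutive fields, which makes the emitted fluence per unit scan length
# exactly proportional to 1/pitch.

#' CT scan protocol
#'
#' @param kvp tube potential (kV)
#' @param mas tube current-time product per rotation (mAs)
#' @param collimation `c(n_slices, slice_width_mm)`; total beam width at
#'   isocenter is `n_slices * slice_width_mm`
#' @param mode "axial" (3DCT) or "helical" (4DCT)
#' @param pitch table travel per rotation / beam width (helical only)
#' @param rotation_time gantry rotation time (s)
#' @param scan_range `c(z_start, z_end)` planned coverage (mm)
#' @return object of class `scan_protocol`
#' @export
#' @examples
#' # the study's 4DCT protocol: 120 kV, 100 mAs, pitch 0.059, 0.44 s
#' scan_protocol(120, 100, c(16, 1.5), "helical", pitch = 0.059,
#'               rotation_time = 0.44, scan_range = c(0, 100))
scan_protocol <- function(kvp = 120, mas = 100, collimation = c(16, 1.5),
                          mode = c("helical", "axial"), pitch = NULL,
                          rotation_time = 0.44, scan_range = c(0, 100)) {
  mode <- match.arg(mode)
  stopifnot(kvp > 0, mas > 0, length(collimation) == 2,
            all(collimation > 0), length(scan_range) == 2)
  if (scan_range[2] < scan_range[1]) stop("z_end must be >= z_start")
  if (mode == "helical") {
    if (is.null(pitch)) pitch <- 0.059
    if (pitch <= 0) stop("pitch must be > 0 for helical mode")
  }
  structure(list(kvp = kvp, mas = mas, collimation = collimation,
                 beam_width = collimation[1] * collimation[2],
                 mode = mode, pitch = pitch, rotation_time = rotation_time,
                 scan_range = as.numeric(scan_range)),
            class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf("<scan_protocol> %s %g kV %g mAs, %g x %g mm (W = %g mm)%s, z [%g, %g] mm\n",
              x$mode, x$kvp, x$mas, x$collimation[1], x$collimation[2],
              x$beam_width,
              if (x$mode == "helical") sprintf(", pitch %g", x$pitch) else "",
              x$scan_range[1], x$scan_range[2]))
  invisible(x)
}

#' Load a packaged or user-supplied x-ray spectrum
#'
#' Returns the tabulated tungsten-anode spectrum for the requested tube
#' potential (1 keV bins, nominal inherent filtration), normalized to unit
#' sum.  The packaged set currently covers 120 kVp; other potentials require
#' a user-supplied two-column text file (energy keV, relative fluence;
#' comment lines start with '#').
#'
#' @param kvp tube potential (kV)
#' @param file optional path to a user spectrum table
#' @return data.frame with columns `energy_kev`, `fluence` (sums to 1)
#' @export
load_spectrum <- function(kvp = 120, file = NULL) {
  if (is.null(file)) {
    if (kvp != 120)
      stop("no packaged spectrum for ", kvp,
           " kVp; supply a spectrum file")
    file <- system.file("extdata", "spectrum_120kvp.txt",
                        package = "ctdosim", mustWork = TRUE)
  }
  tab <- read.table(file, comment.char = "#",
                    col.names = c("energy_kev", "fluence"))
  if (nrow(tab) == 0 || all(tab$fluence <= 0)) stop("empty spectrum")
  if (any(tab$fluence < 0)) stop("negative fluence in spectrum")
  tab$fluence <- tab$fluence / sum(tab$fluence)
  tab
}

#' kV source model: spectrum plus fan-beam geometry
#'
#' @param spectrum data.frame from [load_spectrum()] (energy_kev, fluence)
#' @param sad source-to-axis distance (mm); wide-bore default
#' @param fan_half_angle in-plane fan half-angle (degrees)
#' @param focal_radius radius of the extended circular focal spot (mm)
#' @param beam_width longitudinal collimation width W at isocenter (mm)
#' @return object of class `source_model`
#' @export
source_model <- function(spectrum = load_spectrum(120), sad = 645,
                         fan_half_angle = 28, focal_radius = 1.2,
                         beam_width = 24) {
  stopifnot(all(spectrum$fluence >= 0), any(spectrum$fluence > 0),
            sad > 0, fan_half_angle > 0, beam_width > 0, focal_radius >= 0)
  spectrum$fluence <- spectrum$fluence / sum(spectrum$fluence)
  structure(list(spectrum = spectrum, sad = sad,
                 fan_half_angle = fan_half_angle,
                 focal_radius = focal_radius, beam_width = beam_width),
            class = "source_model")
}

#' Source model matching a protocol's collimation
#' @param protocol a [scan_protocol()]
#' @param ... passed to [source_model()]
#' @return a [source_model()] with `beam_width` set from the protocol
#' @export
source_for_protocol <- function(protocol, ...) {
  source_model(spectrum = load_spectrum(protocol$kvp),
               beam_width = protocol$beam_width, ...)
}

new_fields <- function(angle, z, weight, protocol) {
  structure(data.frame(angle_deg = angle %% 360, iso_z = z, weight = weight),
            protocol = protocol, class = c("beam_fields", "data.frame"))
}

#' Axial (3DCT) beam trajectory
#'
#' Twelve coplanar fields at 30 degree intervals per rotation, all sharing
#' one isocenter z; successive rotations step by the full beam width so axial
#' coverage is contiguous.  Rotations continue until the scan range is
#' covered (at least one rotation).
#'
#' @param protocol a [scan_protocol()] with `mode = "axial"`
#' @return ordered `beam_fields` data.frame (angle_deg, iso_z, weight) with
#'   the protocol attached as an attribute; weight is mAs per field
#'   (mAs per rotation / 12)
#' @export
axial_fields <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (protocol$mode != "axial") stop("protocol mode is not axial")
  W <- protocol$beam_width
  len <- diff(protocol$scan_range)
  n_rot <- max(1L, ceiling(len / W))
  if (len < W)
    warning("scan range shorter than one beam width: single rotation")
  z <- protocol$scan_range[1] + W / 2 + (seq_len(n_rot) - 1) * W
  angles <- seq(0, 330, by = 30)
  new_fields(rep(angles, times = n_rot), rep(z, each = 12),
             protocol$mas / 12, protocol)
}

#' Helical (4DCT) beam trajectory
#'
#' Fields advance 30 degrees in gantry angle and `pitch * W / 12` in
#' isocenter z between consecutive fields.  By default the trajectory spans
#' exactly the prescribed scan range, so the emitted fluence per unit length
#' is 1/pitch times the axial mode's and mode comparisons at equal mAs are
#' bounded by 1/pitch; `over_range = TRUE` additionally extends the
#' trajectory by half a beam width at each end (real scanners over-range so
#' edge slices are fully irradiated, at the cost of extra dose).
#'
#' @param protocol a [scan_protocol()] with `mode = "helical"`
#' @param over_range extend the trajectory by W/2 at each end
#' @return ordered `beam_fields` data.frame; weight is mAs per field
#' @export
helical_fields <- function(protocol, over_range = FALSE) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (protocol$mode != "helical") stop("protocol mode is not helical")
  if (protocol$pitch <= 0) stop("pitch must be > 0")
  W <- protocol$beam_width
  dz <- protocol$pitch * W / 12
  z0 <- protocol$scan_range[1] - if (over_range) W / 2 else 0
  z1 <- protocol$scan_range[2] + if (over_range) W / 2 else 0
  n <- floor((z1 - z0) / dz) + 1L
  i <- seq_len(n) - 1L
  new_fields((i * 30) %% 360, z0 + i * dz, protocol$mas / 12, protocol)
}

#' Sample photons from a source model for one beam field
#'
#' Energy is drawn from the spectrum's discrete distribution; the emission
#' point is sampled uniformly on the circular focal disc at the source
#' position for the field's gantry angle; the direction aims at a point
#' sampled uniformly over the collimated aperture (fan width x longitudinal
#' width) at the isocenter plane, so every ray passes through the aperture.
#'
#' @param source a [source_model()]
#' @param field one row of a `beam_fields` frame (or a list with `angle_deg`,
#'   `iso_z`)
#' @param n number of photons
#' @param iso_xy in-plane isocenter position (mm)
#' @return data.frame: position (x,y,z), unit direction (ux,uy,uz),
#'   energy_kev, weight (= 1)
#' @export
sample_photon <- function(source, field, n = 1, iso_xy = c(0, 0)) {
  stopifnot(inherits(source, "source_model"))
  sp <- source$spectrum
  if (nrow(sp) == 0 || all(sp$fluence == 0)) stop("empty spectrum")
  energy <- sp$energy_kev[sample.int(nrow(sp), n, replace = TRUE,
                                     prob = sp$fluence)]
  th <- field$angle_deg * pi / 180
  s0 <- c(iso_xy[1] + source$sad * cos(th),
          iso_xy[2] + source$sad * sin(th), field$iso_z)
  e1 <- c(-sin(th), cos(th), 0)          # tangential, in-plane
  # focal disc offsets (uniform on disc)
  r <- source$focal_radius * sqrt(runif(n))
  psi <- runif(n, 0, 2 * pi)
  fx <- r * cos(psi); fz <- r * sin(psi)
  px <- s0[1] + fx * e1[1]
  py <- s0[2] + fx * e1[2]
  pz <- s0[3] + fz
  # aim points uniform over the aperture at the isocenter plane
  half_fan <- source$sad * tan(source$fan_half_angle * pi / 180)
  t_off <- runif(n, -half_fan, half_fan)
  z_off <- runif(n, -source$beam_width / 2, source$beam_width / 2)
  tx <- iso_xy[1] + t_off * e1[1]
  ty <- iso_xy[2] + t_off * e1[2]
  tz <- field$iso_z + z_off
  dx <- tx - px; dy <- ty - py; dz <- tz - pz
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  data.frame(x = px, y = py, z = pz,
             ux = dx / nrm, uy = dy / nrm, uz = dz / nrm,
             energy_kev = energy, weight = 1)
}
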