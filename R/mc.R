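# R surface of the Monte Carlo engine: scan simulation, unit conversion,
# and batch-statistics uncertainty.
#
# Normalization contract: `run_scan()` returns energy deposits per history
# (independent of the field weights), and records the total field weight
# (mAs-equivalent fluence) of the trajectory.  `energy_to_dose(...,
# scale = "scan")` multiplies by total_weight / mAs, which carries the
# 1/pitch fluence scaling of low-pitch helical scans; absolute cGy comes
# from the CTDI conversion factor (see calibration.R).

xs_matrices <- function(phantom, xs = NULL) {
  if (is.null(xs)) xs <- xs_library(phantom$materials)
  stopifnot(inherits(xs, "xs_library"),
            all(phantom$materials %in% xs$materials))
  sel <- phantom$materials
  rho_max <- vapply(seq_along(sel), function(i) {
    v <- phantom$density[phantom$material == i]
    if (length(v)) max(v) else 0
  }, numeric(1))
  list(photo = xs$photo[, sel, drop = FALSE],
       incoh = xs$incoh[, sel, drop = FALSE],
       coh = xs$coh[, sel, drop = FALSE],
       emin = min(xs$energy), rho_max = rho_max)
}

new_dose_grid <- function(values, batch, unit, phantom, meta) {
  structure(c(list(values = values, batch = batch, unit = unit,
                   dims = dim(values), spacing = phantom$spacing,
                   origin = phantom$origin), meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid>", paste(x$dims, collapse = " x "), "voxels [", x$unit,
      "],", x$n_histories, "histories in", x$n_batches, "batches\n")
  invisible(x)
}

#' Simulate a CT scan: transport photons for every beam field
#'
#' Histories are allocated to fields proportionally to field weight and
#' transported through the phantom with the kerma-approximation kernel.
#' Results are reproducible bit-for-bit for a given seed.
#'
#' @param phantom a [voxel_phantom()]
#' @param fields `beam_fields` from [axial_fields()] or [helical_fields()]
#' @param source a [source_model()]; default derived from the protocol
#'   attached to `fields`
#' @param n_histories number of photon histories (>= 1)
#' @param seed integer RNG seed (per-history substreams are derived from it)
#' @param n_batches history batches for variance estimation (default 10)
#' @param pcut photon cutoff energy (keV); photons at or below it are
#'   absorbed locally (default 10)
#' @param tracking "woodcock" (delta tracking, default) or "raystep"
#'   (voxel-by-voxel stepping, kept as an independent cross-check)
#' @param iso_xy in-plane isocenter (mm); default the phantom grid centre
#' @param xs optional [xs_library()] override
#' @return a `dose_grid` (unit `keV/voxel/history`) with per-batch deposit
#'   matrix, energy-balance accounting (emitted/deposited/escaped per batch)
#'   and the trajectory's `total_weight` (mAs-equivalent)
#' @export
run_scan <- function(phantom, fields, source = NULL, n_histories = 1e5,
                     seed = 1, n_batches = 10, pcut = 10,
                     tracking = c("woodcock", "raystep"), iso_xy = NULL,
                     xs = NULL) {
  tracking <- match.arg(tracking)
  stopifnot(inherits(phantom, "voxel_phantom"), n_histories >= 1,
            n_batches >= 1)
  protocol <- attr(fields, "protocol")
  if (is.null(source)) {
    if (is.null(protocol)) stop("no source given and fields carry no protocol")
    source <- source_for_protocol(protocol)
  }
  fields <- as.data.frame(fields)
  if (nrow(fields) == 0) stop("fields must be non-empty")
  w <- fields$weight
  if (sum(w) <= 0) stop("zero total field weight")
  mas <- if (!is.null(protocol)) protocol$mas else 12 * mean(w)
  if (is.null(iso_xy)) {
    iso_xy <- c(mean(range(voxel_centers(phantom, 1))),
                mean(range(voxel_centers(phantom, 2))))
  }
  xm <- xs_matrices(phantom, xs)
  sp <- source$spectrum
  res <- cpp_run_scan(
    as.numeric(phantom$density), as.integer(phantom$material - 1L),
    dim(phantom$density), phantom$spacing, phantom$origin,
    xm$photo, xm$incoh, xm$coh, xm$emin, xm$rho_max,
    sp$energy_kev, cumsum(sp$fluence) / sum(sp$fluence),
    as.matrix(fields[, c("angle_deg", "iso_z", "weight")]),
    cumsum(w) / sum(w), source$sad, source$fan_half_angle,
    source$focal_radius, source$beam_width, iso_xy[1], iso_xy[2],
    as.integer(n_histories), as.integer(n_batches), pcut, seed,
    tracking == "woodcock")
  if (res$n_bad > 0)
    warning(res$n_bad, " histories aborted with non-finite state")
  h <- 0:(n_histories - 1)
  n_per_batch <- tabulate(floor(h * n_batches / n_histories) + 1L, n_batches)
  batch <- sweep(res$deposit, 2, pmax(n_per_batch, 1), `/`)
  values <- array(rowSums(res$deposit) / n_histories, dim(phantom$density))
  new_dose_grid(values, batch, "keV/voxel/history", phantom,
                list(n_histories = as.integer(n_histories),
                     n_batches = as.integer(n_batches),
                     n_per_batch = n_per_batch,
                     total_weight = sum(w), mas = mas, seed = seed,
                     tracking = tracking, pcut = pcut,
                     emitted = res$emitted, deposited = res$deposited,
                     escaped = res$escaped, n_bad = res$n_bad))
}

#' Trace a monoenergetic pencil beam through a phantom
#'
#' Test/diagnostic interface to the transport kernel: fires `n` photons of
#' one energy from a point along a fixed direction and reports the deposit
#' grid, the depth of each photon's first real interaction, and the energy
#' balance.
#'
#' @inheritParams run_scan
#' @param energy_kev photon energy
#' @param n number of histories
#' @param start,direction emission point (mm) and unit direction
#' @return list: `dose_grid`, `first_depth` (NA where the photon escaped
#'   uncollided), `emitted`, `deposited`, `escaped` (keV), `n_bad`
#' @export
trace_pencil <- function(phantom, energy_kev, n, seed = 1,
                         start = NULL, direction = c(1, 0, 0), pcut = 10,
                         tracking = c("woodcock", "raystep"), xs = NULL) {
  tracking <- match.arg(tracking)
  stopifnot(inherits(phantom, "voxel_phantom"), n >= 1)
  if (is.null(start)) {
    start <- c(min(voxel_centers(phantom, 1)) - phantom$spacing[1],
               mean(range(voxel_centers(phantom, 2))),
               mean(range(voxel_centers(phantom, 3))))
  }
  direction <- direction / sqrt(sum(direction^2))
  xm <- xs_matrices(phantom, xs)
  res <- cpp_pencil(as.numeric(phantom$density),
                    as.integer(phantom$material - 1L), dim(phantom$density),
                    phantom$spacing, phantom$origin, xm$photo, xm$incoh,
                    xm$coh, xm$emin, xm$rho_max, energy_kev, as.integer(n),
                    seed, start, direction, pcut, tracking == "woodcock")
  res$deposit <- array(res$deposit, dim(phantom$density))
  res
}

#' Sample Compton scattered-photon energies
#'
#' Draws scattered energies from the Klein-Nishina distribution with the
#' engine's own sampler (Kahn's rejection method); the independent oracle is
#' [kn_mean_scatter_fraction()].
#'
#' @param energy_kev incident photon energy
#' @param n number of samples
#' @param seed RNG seed
#' @return vector of scattered photon energies (keV)
#' @export
sample_compton <- function(energy_kev, n, seed = 1) {
  cpp_sample_compton(energy_kev, as.integer(n), seed)
}

#' Convert energy deposits to dose
#'
#' Per-voxel dose = deposited energy / (density x voxel volume).  With
#' `scale = "scan"` (default) the per-history deposit is multiplied by the
#' trajectory's total field weight divided by the per-rotation mAs, so doses
#' from scans with different numbers of fields (e.g. different pitches)
#' compare on a physical fluence scale; absolute cGy additionally requires
#' the CTDI conversion factor ([to_absolute()]).
#'
#' @param dose a `dose_grid` from [run_scan()] (unit keV/voxel/history)
#' @param phantom the phantom the scan was run on
#' @param scale "scan" or "per_history"
#' @return a `dose_grid` with unit `keV/g` (per mAs at scan scale)
#' @export
energy_to_dose <- function(dose, phantom, scale = c("scan", "per_history")) {
  scale <- match.arg(scale)
  stopifnot(inherits(dose, "dose_grid"), dose$unit == "keV/voxel/history",
            inherits(phantom, "voxel_phantom"))
  if (!identical(dose$dims, dim(phantom$density)))
    stop("dose grid and phantom are not congruent")
  vol_cm3 <- prod(phantom$spacing) / 1000
  mass_g <- phantom$density * vol_cm3
  bad <- mass_g == 0 & dose$values > 0
  if (any(bad)) stop("energy deposited in zero-density voxel")
  inv_mass <- ifelse(mass_g > 0, 1 / mass_g, 0)
  k <- if (scale == "scan") dose$total_weight / dose$mas else 1
  out <- dose
  out$values <- dose$values * inv_mass * k
  out$batch <- dose$batch * as.numeric(inv_mass) * k
  out$unit <- "keV/g"
  out$scale <- scale
  out
}

#' Mean dose over a region with batch-statistics uncertainty
#'
#' @param dose a `dose_grid`
#' @param mask an [organ_mask()] or logical array congruent with the grid
#' @return list with `mean`, `sigma` (1 standard error of the mean from
#'   history batches) in the grid's unit
#' @export
region_mean <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"))
  m <- if (inherits(mask, "organ_mask")) mask$mask else mask
  if (!identical(dim(m), dose$dims)) stop("mask not congruent with dose grid")
  if (!any(m)) stop("empty region")
  idx <- which(m)
  batch_means <- colMeans(dose$batch[idx, , drop = FALSE])
  list(mean = mean(dose$values[idx]),
       sigma = sd(batch_means) / sqrt(dose$n_batches))
}

#' Relative statistical uncertainty of a region's mean dose
#'
#' One-sigma relative standard error of the mean dose over a region,
#' estimated from history-batch statistics.  The study's convergence
#' criterion is a value below 2% at 500,000 histories.
#'
#' @inheritParams region_mean
#' @return fraction (e.g. 0.012 for 1.2%); NA with a warning if the region
#'   mean is zero
#' @export
relative_uncertainty <- function(dose, mask) {
  if (dose$n_batches < 2) stop("need >= 2 batches for uncertainty")
  rm_ <- region_mean(dose, mask)
  if (rm_$mean == 0) {
    warning("zero mean dose in region: uncertainty undefined")
    return(NA_real_)
  }
  rm_$sigma / rm_$mean
}
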