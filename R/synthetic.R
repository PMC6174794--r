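# Synthetic thorax phantoms and patient cohorts with the statistical
# structure of the study (102 patients, 51/51 sex split, ages 6-93,
# effective diameters 184.5-465.1 mm), so every pipeline stage runs without
# external data.  Organ shapes are parametric quadrics/tubes, not anatomy:
# the pipeline needs dose ordering and mask bookkeeping, not realism.

#' Parametric thorax phantom specification
#'
#' @param diameter target effective diameter (mm), within [100, 600]
#' @param aspect AP/LAT aspect ratio of the body ellipse
#' @param voxel voxel size (dx, dy, dz) mm
#' @param length phantom length along the table axis (mm)
#' @param skin_thickness skin shell thickness (mm), at least one in-plane
#'   voxel
#' @param lung_density lung mass density (g/cm3)
#' @return object of class `thorax_spec`
#' @export
thorax_spec <- function(diameter = 300, aspect = 0.75, voxel = c(2.5, 2.5, 5),
                        length = 200, skin_thickness = 2.5,
                        lung_density = 0.26) {
  voxel <- rep(as.numeric(voxel), length.out = 3)
  if (diameter < 100 || diameter > 600)
    stop("diameter must be within [100, 600] mm")
  if (skin_thickness < max(voxel[1:2]))
    stop("skin thickness must be >= 1 in-plane voxel")
  structure(list(diameter = diameter, aspect = aspect, voxel = voxel,
                 length = length, skin_thickness = skin_thickness,
                 lung_density = lung_density),
            class = "thorax_spec")
}

ellipse_polygon <- function(a, b, z = 0, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  body_contour(a * cos(th), b * sin(th), z)
}

#' Build a synthetic thorax phantom with organ masks
#'
#' Elliptical soft-tissue body cylinder of the requested effective diameter
#' containing two ellipsoidal lungs, an ellipsoidal heart, a posterior
#' spinal-cord cylinder inside a bone annulus, midline trachea (air lumen)
#' and esophagus tubes, and an outer skin shell.  Organ masks are pairwise
#' disjoint; all are subsets of the body.
#'
#' @param spec a [thorax_spec()]
#' @param mip if TRUE, inflate lung density toward soft tissue to mimic
#'   simulating on a maximum-intensity-projection volume (sensitivity hook
#'   for respiration-induced density bias)
#' @return list: `phantom` ([voxel_phantom()]), `masks` (named list of
#'   [organ_mask()]: body, skin, lungs, heart, esophagus, trachea,
#'   spinal_cord), `contour` (reference-slice body polygon),
#'   `effective_diameter` (measured from the voxelized body),
#'   `scan_range` (organ extent plus 20 mm margin), `spec`
#' @export
make_thorax_phantom <- function(spec = thorax_spec(), mip = FALSE) {
  stopifnot(inherits(spec, "thorax_spec"))
  d <- spec$diameter
  a <- d / (2 * sqrt(spec$aspect))   # LAT semi-axis
  b <- spec$aspect * a               # AP semi-axis
  vx <- spec$voxel
  nx <- ceiling((2 * a + 20) / vx[1])
  ny <- ceiling((2 * b + 20) / vx[2])
  nz <- ceiling(spec$length / vx[3])
  xs <- (seq_len(nx) - (nx + 1) / 2) * vx[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * vx[2]
  zs <- (seq_len(nz) - 0.5) * vx[3]
  L <- spec$length

  X <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))

  in_ellipse <- function(cx, cy, sa, sb) ((X - cx) / sa)^2 + ((Y - cy) / sb)^2 <= 1
  in_ellipsoid <- function(cx, cy, cz, sa, sb, sc)
    ((X - cx) / sa)^2 + ((Y - cy) / sb)^2 + ((Z - cz) / sc)^2 <= 1
  in_tube <- function(cx, cy, r, z0, z1)
    (X - cx)^2 + (Y - cy)^2 <= r^2 & Z >= z0 & Z <= z1

  body <- in_ellipse(0, 0, a, b)
  organ_z <- c(0.1 * L, 0.9 * L)
  z0 <- organ_z[1]; z1 <- organ_z[2]

  skin <- body & !in_ellipse(0, 0, a - spec$skin_thickness,
                             b - spec$skin_thickness)
  r_spine <- max(12, 0.05 * d)
  # the trachea organ is the cartilage wall; the air lumen inside it carries
  # no mask (analog kerma scoring in low-density air is meaningless)
  r_lumen <- max(7, 0.025 * d)
  lumen <- in_tube(0, -0.15 * b, r_lumen, 0.5 * L, z1)
  raw <- list(
    trachea = in_tube(0, -0.15 * b, r_lumen + 2.5, 0.5 * L, z1) & !lumen,
    esophagus = in_tube(0, 0.25 * b, 5, z0, z1),
    spinal_cord = in_tube(0, 0.62 * b, 4.5, z0, z1),
    bone = in_tube(0, 0.62 * b, r_spine, z0, z1) &
      !in_tube(0, 0.62 * b, 5.0, z0, z1),
    heart = in_ellipsoid(-0.05 * a, -0.15 * b, 0.45 * L,
                         0.20 * a, 0.22 * b, 0.175 * L),
    lungs = in_ellipsoid(-0.5 * a, -0.05 * b, 0.5 * L,
                         0.33 * a, 0.60 * b, 0.40 * L) |
      in_ellipsoid(0.5 * a, -0.05 * b, 0.5 * L,
                   0.33 * a, 0.60 * b, 0.40 * L)
  )
  # enforce pairwise disjointness by priority, and keep everything inside
  # the body and off the skin shell
  interior <- body & !skin
  lumen <- lumen & interior
  taken <- lumen
  for (nm in names(raw)) {
    raw[[nm]] <- raw[[nm]] & interior & !taken
    taken <- taken | raw[[nm]]
    if (!any(raw[[nm]]))
      stop("organ '", nm, "' does not fit at diameter ", d,
           " mm (constraint: body ellipse ", round(2 * a), " x ",
           round(2 * b), " mm)")
  }

  density <- array(0.00120, c(nx, ny, nz))
  material <- array(1L, c(nx, ny, nz))  # air
  mats <- c("air", "lung", "soft_tissue", "bone")
  set_region <- function(m, dens, mat_id) {
    density[m] <<- dens
    material[m] <<- mat_id
  }
  set_region(body, 1.00, 3L)
  set_region(skin, 1.09, 3L)
  lung_rho <- spec$lung_density * (if (mip) 1.5 else 1)
  set_region(raw$lungs, lung_rho, 2L)
  set_region(raw$heart, 1.05, 3L)
  set_region(raw$bone, 1.40, 4L)
  set_region(raw$spinal_cord, 1.04, 3L)
  set_region(raw$trachea, 1.05, 3L)
  set_region(lumen, 0.00120, 1L)
  set_region(raw$esophagus, 1.00, 3L)

  phantom <- voxel_phantom(density, material, spacing = vx,
                           origin = c(xs[1], ys[1], zs[1]), materials = mats)
  masks <- list(body = organ_mask(body, "body", phantom),
                skin = organ_mask(skin, "skin", phantom))
  for (nm in names(raw))
    if (nm != "bone") masks[[nm]] <- organ_mask(raw[[nm]], nm, phantom)

  k_ref <- which.min(abs(zs - L / 2))
  area <- sum(body[, , k_ref]) * vx[1] * vx[2]
  list(phantom = phantom, masks = masks,
       contour = ellipse_polygon(a, b, zs[k_ref]),
       effective_diameter = 2 * sqrt(area / pi),
       organ_z = organ_z,
       scan_range = c(z0 - 20, z1 + 20),
       spec = spec)
}

#' Generate a synthetic patient cohort
#'
#' Effective diameters are placed as evenly spaced quantiles over the stated
#' range (then permuted), so the generated cohort always represents the full
#' observed size range; ages are uniform; sexes are balanced exactly when n
#' is even and the split is 50/50.
#'
#' @param n number of patients (default 102, the study cohort size)
#' @param diameter_range effective diameter range (mm)
#' @param age_range age range at exposure (years)
#' @param male_fraction fraction of males
#' @param seed RNG seed; the cohort is deterministic given the seed
#' @return data.frame: patient_id, effective_diameter_mm, age, sex
#' @export
make_cohort <- function(n = 102, diameter_range = c(184.5, 465.1),
                        age_range = c(6, 93), male_fraction = 0.5,
                        seed = 1) {
  stopifnot(n >= 1, diff(diameter_range) >= 0, diff(age_range) >= 0)
  set.seed(seed)
  diam <- if (n == 1) mean(diameter_range) else
    seq(diameter_range[1], diameter_range[2], length.out = n)
  n_male <- round(n * male_fraction)
  sex <- c(rep("male", n_male), rep("female", n - n_male))[sample.int(n)]
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             effective_diameter_mm = diam[sample.int(n)],
             age = round(runif(n, age_range[1], age_range[2])),
             sex = sex)
}

#' Printed size-dose regression coefficients of the study
#'
#' Intercept (cGy), slope (cGy/mm) and R^2 of the linear organ-dose vs
#' effective-diameter fits for each organ and protocol; used as generating
#' truth for fast synthetic dose tables.
#'
#' @return data.frame: organ, protocol, intercept_cgy, slope_cgy_per_mm,
#'   r_squared
#' @export
study_fit_coefficients <- function() {
  rbind(
    data.frame(organ = c("trachea", "lungs", "spinal_cord", "esophagus",
                         "heart", "skin"),
               protocol = "3DCT",
               intercept_cgy = c(2.43, 2.04, 1.91, 2.21, 2.27, 1.63),
               slope_cgy_per_mm = c(-0.0045, -0.0039, -0.0035, -0.0042,
                                    -0.0044, -0.003),
               r_squared = c(0.70, 0.84, 0.61, 0.67, 0.73, 0.69)),
    data.frame(organ = c("trachea", "lungs", "spinal_cord", "esophagus",
                         "heart", "skin"),
               protocol = "4DCT",
               intercept_cgy = c(30.95, 25.90, 24.24, 29.17, 29.43, 17.17),
               slope_cgy_per_mm = c(-0.0574, -0.0491, -0.0435, -0.0559,
                                    -0.0576, -0.0278),
               r_squared = c(0.67, 0.83, 0.60, 0.67, 0.71, 0.79))
  )
}

#' Synthesize an organ-dose table from linear truth coefficients
#'
#' dose = intercept + slope * diameter + Gaussian noise, floored at zero:
#' a fast fixture for the regression and risk stages that bypasses the
#' transport engine.
#'
#' @param cohort a [make_cohort()] data.frame
#' @param truth coefficient table (default [study_fit_coefficients()])
#' @param noise_sd_frac noise standard deviation as a fraction of each
#'   organ/protocol's cohort-mean dose (default 0.10)
#' @param seed RNG seed
#' @return data.frame: patient_id, organ, protocol, dose_cgy, sigma_cgy,
#'   effective_diameter_mm, age, sex
#' @export
make_dose_table <- function(cohort, truth = study_fit_coefficients(),
                            noise_sd_frac = 0.10, seed = 1) {
  set.seed(seed)
  out <- NULL
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    mu <- tr$intercept_cgy + tr$slope_cgy_per_mm *
      cohort$effective_diameter_mm
    sdv <- noise_sd_frac * mean(mu)
    dose <- pmax(mu + rnorm(nrow(cohort), 0, sdv), 0)
    out <- rbind(out, data.frame(
      patient_id = cohort$patient_id, organ = tr$organ,
      protocol = tr$protocol, dose_cgy = dose, sigma_cgy = sdv,
      effective_diameter_mm = cohort$effective_diameter_mm,
      age = cohort$age, sex = cohort$sex))
  }
  out
}
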