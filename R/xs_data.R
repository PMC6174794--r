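# Photon cross-section library for the kV transport kernel.
#
# Construction: total mass attenuation coefficients are anchored to the
# standard published water / dry-air / cortical-bone tabulations at
# 10-150 keV.  The incoherent (Compton) part is the closed-form Klein-Nishina
# total cross section per electron times the material electron density times
# a smooth low-energy binding correction; the coherent (Rayleigh) part is an
# anchored ~E^-1.9 power law; the photoelectric part is the remainder, so the
# partials sum to the anchored total exactly at the anchor energies.  Soft
# tissue and lung reuse the water total curve (equal within ~1% over the CT
# energy range); lung differs from soft tissue only by density.

.xs_anchor_energy <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150)

.xs_anchor_total <- list(
  water       = c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059,
                  0.1837, 0.1707, 0.1505),
  air         = c(5.120, 1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875,
                  0.1662, 0.1541, 0.1356),
  bone        = c(28.51, 9.032, 4.001, 1.331, 0.6655, 0.4242, 0.3148,
                  0.2229, 0.1855, 0.1480)
)
.xs_total_alias <- c(water = "water", air = "air", bone = "bone",
                     soft_tissue = "water", lung = "water")

# electrons per gram = N_A * Z/A
.xs_z_over_a <- c(water = 0.55509, air = 0.49919, bone = 0.51478,
                  soft_tissue = 0.55121, lung = 0.55048)

# incoherent-scattering binding correction (fraction of the free-electron
# Klein-Nishina value), smooth and common to the low-Z materials
.xs_s_corr <- c(0.780, 0.860, 0.905, 0.945, 0.965, 0.975, 0.982,
                0.990, 0.994, 0.998)

# coherent share of the non-Compton remainder at 60 keV
.xs_rc60 <- c(water = 0.22, air = 0.22, bone = 0.10,
              soft_tissue = 0.22, lung = 0.22)

#' Klein-Nishina total cross section per electron
#'
#' Closed-form integrated Klein-Nishina cross section for Compton scattering
#' off a free electron.
#'
#' @param energy_kev photon energy in keV
#' @return cross section in cm^2 per electron
#' @export
kn_total_cs <- function(energy_kev) {
  k <- energy_kev / 510.99895
  l <- log1p(2 * k)
  two_pi_re2 <- 4.989569e-25
  two_pi_re2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - l / k) +
                  l / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

#' Mean scattered-photon energy fraction after Compton scattering
#'
#' Numerical integration of the Klein-Nishina differential cross section in
#' scattered energy; used for the kerma energy-transfer column and as the
#' independent oracle for the engine's Compton sampler.
#'
#' @param energy_kev incident photon energy in keV
#' @return mean of E'/E over the Klein-Nishina distribution
#' @export
kn_mean_scatter_fraction <- function(energy_kev) {
  vapply(energy_kev, function(E) {
    k <- E / 510.99895
    # x = E/E' in [1, 1+2k]; KN density in x: (1/x^2)(x + 1/x - 1 + cos^2)
    dens <- function(x) {
      ct <- 1 - (x - 1) / k
      (1 / x^2) * (x + 1 / x - 1 + ct^2)
    }
    norm <- integrate(dens, 1, 1 + 2 * k, rel.tol = 1e-10)$value
    mean_inv <- integrate(function(x) dens(x) / x, 1, 1 + 2 * k,
                          rel.tol = 1e-10)$value
    mean_inv / norm
  }, numeric(1))
}

#' Photon interaction cross-section library
#'
#' Builds mass attenuation coefficient tables (cm^2/g) for the packaged
#' materials on a 1 keV grid, split into photoelectric, incoherent (Compton)
#' and coherent (Rayleigh) components plus a mass energy-transfer column for
#' kerma.  The total is defined as the sum of the partials and matches the
#' published water/air/bone totals at the anchor energies.
#'
#' @param materials character vector of material names; default all packaged
#'   materials (`air`, `lung`, `soft_tissue`, `bone`, `water`)
#' @param energy_kev energy grid in keV (default 10:120, the transport range
#'   between the 10 keV photon cutoff and the 120 kVp endpoint)
#' @return object of class `xs_library`: list with `energy`, `materials`, and
#'   matrices `photo`, `incoh`, `coh`, `total`, `mutr` (energy x material)
#' @export
xs_library <- function(materials = c("air", "lung", "soft_tissue", "bone",
                                     "water"),
                       energy_kev = 10:120) {
  stopifnot(all(materials %in% names(.xs_total_alias)))
  aE <- .xs_anchor_energy
  loglog <- function(y, xo) exp(approx(log(aE), log(y), log(xo))$y)
  nE <- length(energy_kev)
  nm <- length(materials)
  photo <- incoh <- coh <- matrix(0, nE, nm,
                                  dimnames = list(NULL, materials))
  for (m in materials) {
    tot_a <- .xs_anchor_total[[.xs_total_alias[[m]]]]
    inc_a <- kn_total_cs(aE) * 6.02214076e23 * .xs_z_over_a[[m]] * .xs_s_corr
    rem60 <- tot_a[aE == 60] - inc_a[aE == 60]
    coh_a <- .xs_rc60[[m]] * rem60 * (60 / aE)^1.9
    pho_a <- pmax(tot_a - inc_a - coh_a, 1e-8)
    photo[, m] <- loglog(pho_a, energy_kev)
    incoh[, m] <- loglog(inc_a, energy_kev)
    coh[, m] <- loglog(coh_a, energy_kev)
  }
  total <- photo + incoh + coh
  mutr <- photo + incoh * (1 - kn_mean_scatter_fraction(energy_kev))
  structure(list(energy = energy_kev, materials = materials, photo = photo,
                 incoh = incoh, coh = coh, total = total, mutr = mutr),
            class = "xs_library")
}

#' Look up a mass attenuation coefficient
#'
#' @param xs an [xs_library()]
#' @param material material name
#' @param energy_kev energies (keV), interpolated linearly on the fine grid
#' @param component one of "total", "photo", "incoh", "coh", "mutr"
#' @return mass attenuation coefficient(s) in cm^2/g
#' @export
mu_rho <- function(xs, material, energy_kev, component = "total") {
  stopifnot(inherits(xs, "xs_library"), material %in% xs$materials,
            component %in% c("total", "photo", "incoh", "coh", "mutr"))
  approx(xs$energy, xs[[component]][, material], energy_kev, rule = 2)$y
}

#' @export
print.xs_library <- function(x, ...) {
  cat("<xs_library>", length(x$materials), "materials,",
      length(x$energy), "energies", paste0("[", min(x$energy), ", ",
                                           max(x$energy), "] keV\n"))
  invisible(x)
}
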