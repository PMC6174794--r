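test_that("axial trajectories tile the scan range with 12-field rotations", {
  pr <- scan_protocol(120, 100, c(16, 1.5), "axial", scan_range = c(0, 72))
  f <- axial_fields(pr)
  expect_equal(nrow(f), 36)  # ceil(72/24) rotations x 12 fields
  expect_equal(length(unique(f$iso_z)), 3)
  expect_equal(diff(unique(f$iso_z)), c(24, 24))
  expect_setequal(unique(f$angle_deg), seq(0, 330, by = 30))
  expect_true(all(table(f$angle_deg) == 3))
  expect_equal(sum(f$weight), 3 * 100)  # mAs per rotation x rotations

  pr0 <- scan_protocol(120, 100, c(16, 1.5), "axial", scan_range = c(10, 10))
  expect_warning(f0 <- axial_fields(pr0), "single rotation")
  expect_equal(nrow(f0), 12)
})

test_that("helical trajectories advance by pitch * W / 12 per field", {
  pr1 <- scan_protocol(120, 100, c(16, 1.5), "helical", pitch = 1,
                       scan_range = c(0, 100))
  f1 <- helical_fields(pr1)
  expect_equal(unique(round(diff(f1$iso_z), 12)), 2.0)
  expect_equal(f1$angle_deg[1:14], c(seq(0, 330, 30), 0, 30))

  prp <- scan_protocol(120, 100, c(16, 1.5), "helical", pitch = 0.059,
                       scan_range = c(0, 100))
  fp <- helical_fields(prp)
  expect_equal(unique(round(diff(fp$iso_z), 12)), 0.118)

  # field count (fluence per unit length) scales as 1/pitch
  pr01 <- scan_protocol(120, 100, c(16, 1.5), "helical", pitch = 0.1,
                        scan_range = c(0, 100))
  expect_equal(nrow(helical_fields(pr01)) / nrow(f1), 10, tolerance = 0.02)

  # default trajectory spans exactly the scan range; over-ranging adds half
  # a beam width at each end
  expect_equal(min(f1$iso_z), 0)
  expect_equal(max(f1$iso_z) - min(f1$iso_z), 100)
  f1o <- helical_fields(pr1, over_range = TRUE)
  expect_equal(min(f1o$iso_z), -12)
  expect_equal(max(f1o$iso_z), 112)

  expect_error(scan_protocol(120, 100, c(16, 1.5), "helical", pitch = -1),
               "pitch")
})

test_that("the packaged 120 kVp spectrum is normalized and physically bounded", {
  sp <- load_spectrum(120)
  expect_equal(sum(sp$fluence), 1, tolerance = 1e-12)
  expect_true(all(sp$fluence >= 0))
  expect_lte(max(sp$energy_kev[sp$fluence > 0]), 120)
  mean_e <- sum(sp$energy_kev * sp$fluence)
  expect_gt(mean_e, 55)
  expect_lt(mean_e, 75)
  expect_error(load_spectrum(80), "packaged")
})

test_that("photon sampling follows the spectrum and stays in the aperture", {
  field <- list(angle_deg = 37, iso_z = 50)
  mono <- source_model(data.frame(energy_kev = 60, fluence = 1),
                       beam_width = 24)
  set.seed(1)
  p <- sample_photon(mono, field, n = 200)
  expect_true(all(p$energy_kev == 60))
  expect_true(all(abs(sqrt(p$ux^2 + p$uy^2 + p$uz^2) - 1) < 1e-9))
  expect_true(all(p$weight == 1))

  # two-line spectrum: frequencies within 3 sigma binomial
  two <- source_model(data.frame(energy_kev = c(40, 80),
                                 fluence = c(0.25, 0.75)), beam_width = 24)
  set.seed(2)
  n <- 1e5
  p2 <- sample_photon(two, field, n = n)
  phat <- mean(p2$energy_kev == 80)
  expect_lt(abs(phat - 0.75), 3 * sqrt(0.75 * 0.25 / n))

  # packaged spectrum: chi-square goodness of fit at n = 1e5
  src <- source_model()
  set.seed(3)
  ps <- sample_photon(src, field, n = 1e5)
  sp <- src$spectrum
  keep <- sp$fluence > 1e-6
  obs <- tabulate(match(ps$energy_kev, sp$energy_kev), nrow(sp))[keep]
  gof <- suppressWarnings(chisq.test(obs, p = sp$fluence[keep] /
                                       sum(sp$fluence[keep])))
  expect_gt(gof$p.value, 1e-3)

  # every ray passes inside the collimated aperture at the isocenter plane
  th <- field$angle_deg * pi / 180
  ndir <- c(-cos(th), -sin(th), 0)  # central beam direction
  iso <- c(0, 0, field$iso_z)
  tplane <- ((iso[1] - p2$x) * ndir[1] + (iso[2] - p2$y) * ndir[2]) /
    (p2$ux * ndir[1] + p2$uy * ndir[2])
  hx <- p2$x + tplane * p2$ux
  hy <- p2$y + tplane * p2$uy
  hz <- p2$z + tplane * p2$uz
  tang <- hx * (-sin(th)) + hy * cos(th)
  half_fan <- two$sad * tan(two$fan_half_angle * pi / 180)
  expect_true(all(abs(tang) <= half_fan + 1e-6))
  expect_true(all(abs(hz - field$iso_z) <= 12 + 1e-6))
})
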