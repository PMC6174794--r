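test_that("a pencil beam that misses the phantom deposits nothing", {
  ph <- water_box()
  tp <- trace_pencil(ph, 60, 500, seed = 1, direction = c(-1, 0, 0))
  expect_equal(sum(tp$deposit), 0)
  expect_equal(tp$escaped, tp$emitted)
  expect_true(all(is.na(tp$first_depth)))
})

test_that("a purely photoelectric medium absorbs each photon at first collision", {
  ph <- water_box()
  xs <- xs_default()
  xs$incoh[] <- 1e-12
  xs$coh[] <- 1e-12
  xs$total <- xs$photo + xs$incoh + xs$coh
  tp <- trace_pencil(ph, 60, 2000, seed = 5, xs = xs)
  n_int <- sum(!is.na(tp$first_depth))
  expect_equal(tp$deposited, 60 * n_int)
  expect_equal(sum(tp$deposit), 60 * n_int)
  expect_equal(tp$n_bad, 0)
})

test_that("first-interaction free paths in water follow exp(-mu x)", {
  ph <- water_box()
  xs <- xs_default()
  for (E in c(40, 80)) {
    tp <- trace_pencil(ph, E, 5e4, seed = E)
    mu <- mu_rho(xs, "water", E) * 0.1  # per mm, unit density
    d <- tp$first_depth[!is.na(tp$first_depth)]
    d <- d[d < 250]
    ks <- suppressWarnings(
      ks.test(d, function(q) pexp(q, mu) / pexp(250, mu)))
    expect_gt(ks$p.value, 1e-3)
  }
})

test_that("uncollided transmission through 10 cm water matches the 60 keV anchor", {
  ph <- water_box()
  n <- 4e4
  tp <- trace_pencil(ph, 60, n, seed = 7)
  frac <- mean(is.na(tp$first_depth) | tp$first_depth > 100)
  expected <- exp(-0.2059 * 10)
  expect_lt(abs(frac - expected),
            0.02 * expected + 3 * sqrt(expected * (1 - expected) / n))
})

test_that("the Compton sampler reproduces the Klein-Nishina mean scattered energy", {
  for (E in c(60, 100)) {
    s <- sample_compton(E, 2e5, seed = E)
    oracle <- E * kn_mean_scatter_fraction(E)
    expect_lt(abs(mean(s) - oracle) / oracle, 0.01)
    expect_true(all(s >= E / (1 + 2 * E / 510.99895) - 1e-9))
    expect_true(all(s <= E + 1e-9))
  }
})

test_that("energy is conserved per batch through a full scan", {
  th <- thorax300()
  dg <- run_scan(th$phantom, helical_fields(protocol_4d(th$scan_range)),
                 n_histories = 2e4, seed = 11)
  expect_equal(dg$deposited + dg$escaped, dg$emitted, tolerance = 1e-9)
  expect_equal(sum(dg$values) * dg$n_histories, sum(dg$deposited),
               tolerance = 1e-9)
  expect_equal(dg$n_bad, 0)
})

test_that("scans are reproducible and per-history dose is weight-invariant", {
  ct <- ctdi_fix()
  pr <- protocol_3d(c(-12, 12))
  f <- axial_fields(pr)
  a <- run_scan(ct$phantom, f, n_histories = 1e4, seed = 3)
  b <- run_scan(ct$phantom, f, n_histories = 1e4, seed = 3)
  expect_identical(a$values, b$values)
  expect_identical(a$batch, b$batch)

  f2 <- f
  f2$weight <- f$weight * 2
  attr(f2, "protocol") <- pr
  c2 <- run_scan(ct$phantom, f2, n_histories = 1e4, seed = 3)
  expect_identical(c2$values, a$values)       # per-history normalization
  expect_equal(c2$total_weight, 2 * a$total_weight)  # fluence scale doubles
})

test_that("Woodcock tracking agrees with voxel-by-voxel ray stepping", {
  sl <- slab_phantom()
  f <- axial_fields(protocol_3d(c(19, 43)))
  dw <- run_scan(sl, f, n_histories = 4e4, seed = 13,
                 tracking = "woodcock")
  dr <- run_scan(sl, f, n_histories = 4e4, seed = 14,
                 tracking = "raystep")
  body <- sl$density > 0.5
  mw <- region_mean(energy_to_dose(dw, sl), body)
  mr <- region_mean(energy_to_dose(dr, sl), body)
  expect_lt(abs(mw$mean - mr$mean),
            3 * sqrt(mw$sigma^2 + mr$sigma^2) + 1e-12)
  # and in the dense insert specifically
  insert <- sl$material == 3L
  iw <- region_mean(energy_to_dose(dw, sl), insert)
  ir <- region_mean(energy_to_dose(dr, sl), insert)
  expect_lt(abs(iw$mean - ir$mean), 3 * sqrt(iw$sigma^2 + ir$sigma^2))
})

test_that("uncertainty shrinks as 1/sqrt(histories) and handles edge cases", {
  ct <- ctdi_fix()
  f <- axial_fields(protocol_3d(c(-12, 12)))
  body <- ct$phantom$density > 0.5
  d1 <- run_scan(ct$phantom, f, n_histories = 2e4, seed = 17)
  d4 <- run_scan(ct$phantom, f, n_histories = 8e4, seed = 18)
  r1 <- relative_uncertainty(energy_to_dose(d1, ct$phantom), body)
  r4 <- relative_uncertainty(energy_to_dose(d4, ct$phantom), body)
  expect_equal(r1 / r4, 2, tolerance = 0.5)

  # identical batches -> exactly zero uncertainty
  dz <- d1
  dz$batch <- matrix(1, nrow(d1$batch), ncol(d1$batch))
  dz$values <- array(1, dz$dims)
  expect_equal(relative_uncertainty(dz, body), 0)

  # zero-mean region is undefined, not zero
  corner <- array(FALSE, dz$dims)
  corner[1, 1, 1] <- TRUE
  dz$batch[] <- 0
  dz$values[] <- 0
  expect_warning(ru <- relative_uncertainty(dz, corner), "undefined")
  expect_true(is.na(ru))
})

test_that("energy-to-dose conversion divides by voxel mass", {
  ph <- voxel_phantom(array(1, c(2, 1, 1)), array(1L, c(2, 1, 1)),
                      spacing = c(1, 1, 1), materials = "water")
  dg <- run_scan(ph, axial_fields(protocol_3d(c(0, 1))),
                 n_histories = 10, seed = 1)
  dg$values <- array(c(1, 1), c(2, 1, 1))   # 1 keV per voxel
  dg$batch <- matrix(1, 2, dg$n_batches)
  dm <- energy_to_dose(dg, ph, scale = "per_history")
  expect_equal(c(dm$values), c(1000, 1000))  # keV per gram in 1 mm3 water

  ph2 <- ph
  ph2$density[2, 1, 1] <- 0.5
  dm2 <- energy_to_dose(dg, ph2, scale = "per_history")
  expect_equal(dm2$values[2, 1, 1] / dm2$values[1, 1, 1], 2)

  ph3 <- ph
  ph3$density[2, 1, 1] <- 0
  expect_error(energy_to_dose(dg, ph3), "zero-density")
})
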