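test_that("HU calibration hits the air and water anchors and interpolates", {
  hu <- array(c(0, -1000, -500, 50, 2000, -2000), c(6, 1, 1))
  ph <- build_from_hu(hu, spacing = c(1, 1, 1))
  expect_equal(ph$density[1, 1, 1], 1.000)
  expect_equal(ph$materials[ph$material[1, 1, 1]], "soft_tissue")
  expect_equal(ph$density[2, 1, 1], 0.00120)
  expect_equal(ph$materials[ph$material[2, 1, 1]], "air")
  # clamped beyond the table extremes
  expect_equal(ph$density[5, 1, 1], max(material_table()$density))
  expect_equal(ph$density[6, 1, 1], 0.00120)

  # two-point air/water segment: exact linear interpolation
  two <- material_table(hu = c(-1000, 0), density = c(0.00120, 1.000),
                        material = c("air", "water"))
  ph2 <- build_from_hu(hu, spacing = c(1, 1, 1), table = two)
  expect_equal(ph2$density[3, 1, 1], 0.5006, tolerance = 1e-6)
})

test_that("HU-to-density map is monotonic and rejects bad input", {
  hu_grid <- seq(-1100, 1500, by = 7)
  ph <- build_from_hu(array(hu_grid, c(length(hu_grid), 1, 1)),
                      spacing = c(1, 1, 1))
  expect_true(all(diff(c(ph$density)) >= 0))
  expect_error(build_from_hu(array(NaN, c(2, 2, 2)), c(1, 1, 1)),
               "finite")
  expect_error(material_table(hu = c(0, 0), density = c(1, 1),
                              material = c("a", "a")), "increasing")
  expect_error(voxel_phantom(array(1, c(2, 2, 2)), array(1L, c(3, 2, 2)),
                             c(1, 1, 1), materials = "water"),
               "congruent")
})

test_that("contour rasterization reproduces exact and brute-force areas", {
  ph <- voxel_phantom(array(1, c(120, 120, 3)), array(2L, c(120, 120, 3)),
                      spacing = c(1, 1, 1), origin = c(-59.5, -59.5, 0),
                      materials = c("air", "water"))
  # axis-aligned 20 x 20 mm square: exactly 400 voxel centres inside
  sq <- body_contour(c(-10, 10, 10, -10), c(-10, -10, 10, 10), z = 1)
  m <- rasterize_contour(sq, ph, "body")
  expect_equal(sum(m$mask), 400)

  # circle r = 50: matches brute-force point-in-circle count, within 1% of
  # the exact area
  circ <- circle_contour(50, z = 1)
  mc <- rasterize_contour(circ, ph, "body")
  xs <- voxel_centers(ph, 1); ys <- voxel_centers(ph, 2)
  brute <- sum(outer(xs^2, ys^2, `+`) <= 50^2)
  expect_lt(abs(sum(mc$mask) - brute), 0.005 * brute)
  expect_lt(abs(sum(mc$mask) - pi * 50^2), 0.01 * pi * 50^2)

  expect_error(rasterize_contour(circle_contour(5, cx = 500, cy = 500), ph,
                                 "heart"), "heart")
})

test_that("rasterized area converges to polygon area under grid refinement", {
  area_err <- vapply(c(2, 0.5), function(h) {
    n <- ceiling(130 / h)
    ph <- voxel_phantom(array(1, c(n, n, 1)), array(1L, c(n, n, 1)),
                        spacing = c(h, h, 1),
                        origin = c(-(n - 1) / 2 * h, -(n - 1) / 2 * h, 0),
                        materials = "water")
    m <- rasterize_contour(circle_contour(55), ph)
    abs(sum(m$mask) * h^2 - pi * 55^2)
  }, numeric(1))
  expect_lt(area_err[2], area_err[1])
})

test_that("effective diameter is the equal-area circle diameter", {
  expect_equal(effective_diameter(circle_contour(100)), 200,
               tolerance = 1e-3)
  th <- seq(0, 2 * pi, length.out = 2001)[-1]
  ell <- body_contour(100 * cos(th), 150 * sin(th))
  expect_equal(effective_diameter(ell), 2 * sqrt(100 * 150),
               tolerance = 1e-3)
  # invariant under rigid rotation + translation
  phi <- 0.7
  rot <- body_contour(cos(phi) * ell$x - sin(phi) * ell$y + 40,
                      sin(phi) * ell$x + cos(phi) * ell$y - 17)
  expect_equal(effective_diameter(rot), effective_diameter(ell))
  expect_error(effective_diameter(body_contour(c(0, 1, 2), c(0, 1, 2))),
               "degenerate")
})

test_that("CTDI phantom is a homogeneous water cylinder with a resolvable chamber", {
  ct <- make_ctdi_phantom()
  ph <- ct$phantom
  mid <- ph$density[, , 1]
  xs <- voxel_centers(ph, 1)
  water_cols <- xs[apply(mid == 1, 1, any)]
  expect_equal(diff(range(water_cols)), 160, tolerance = 2)
  expect_true(all(ph$density[ph$material == 2L] == 1.0))
  vox_vol <- prod(ph$spacing)
  expect_lt(abs(sum(ct$chamber$mask) * vox_vol - ct$chamber_volume_mm3),
            0.05 * ct$chamber_volume_mm3)
  expect_error(make_ctdi_phantom(voxel = c(25, 25, 3)), "unresolvable")
})
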