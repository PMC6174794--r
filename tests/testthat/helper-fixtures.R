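# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# homogeneous water box, 300 x 52.5 x 52.5 mm, 2.5 mm voxels
water_box <- function() fixture("water_box", function() {
  d <- array(1.0, c(120, 21, 21))
  voxel_phantom(d, array(2L, dim(d)), spacing = c(2.5, 2.5, 2.5),
                materials = c("air", "water"))
})

# two-material slab: first 100 mm water, then 50 mm bone, then water
slab_phantom <- function() fixture("slab_phantom", function() {
  d <- array(1.0, c(100, 25, 25))
  m <- array(2L, dim(d))
  m[41:60, , ] <- 3L
  d[41:60, , ] <- 1.85
  voxel_phantom(d, m, spacing = c(2.5, 2.5, 2.5),
                materials = c("air", "water", "bone"))
})

ctdi_fix <- function() fixture("ctdi", function() make_ctdi_phantom())

thorax300 <- function() fixture("thorax300",
                                function() make_thorax_phantom(thorax_spec(300)))

xs_default <- function() fixture("xs_default", function() xs_library())

protocol_4d <- function(scan_range = c(0, 200))
  scan_protocol(120, 100, c(16, 1.5), "helical", pitch = 0.059,
                rotation_time = 0.44, scan_range = scan_range)

protocol_3d <- function(scan_range = c(0, 200))
  scan_protocol(120, 100, c(16, 1.5), "axial", rotation_time = 0.44,
                scan_range = scan_range)

# circle contour helper
circle_contour <- function(r, cx = 0, cy = 0, z = 0, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  body_contour(cx + r * cos(th), cy + r * sin(th), z)
}
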