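test_that("unit conversions scale correctly and compose to identity", {
  expect_equal(convert_units(25, "uN.m", "N.m"), 2.5e-5)
  expect_equal(convert_units(3, "mN", "N"), 3e-3)
  expect_equal(convert_units(1.5, "kPa", "Pa"), 1500)
  for (u in c("uN.m", "mN.m")) {
    x <- c(0.3, 7, 1e4)
    expect_equal(convert_units(convert_units(x, u, "N.m"), "N.m", u), x)
  }
  expect_error(convert_units(1, "uN.m", "Pa"), "incompatible")
  expect_error(convert_units(1, "furlong", "m"), "unknown unit")
})

test_that("rheometry CSV reader parses, converts units and collapses duplicates", {
  p <- write_temp_csv(data.frame(omega = c(0.1, 1, 10),
                                 torque = c(1e-5, 2e-5, 9e-5)))
  curve <- read_rheometry_csv(p)
  expect_s3_class(curve, "torque_velocity_curve")
  expect_length(curve, 3)
  expect_equal(curve$omega, c(0.1, 1, 10))

  # micro-Newton-metre export
  p2 <- write_temp_csv(data.frame(omega = c(0.1, 1, 10),
                                  torque = c(10, 20, 90)))
  curve2 <- read_rheometry_csv(p2, torque_unit = "uN.m")
  expect_equal(curve2$torque, c(1e-5, 2e-5, 9e-5))

  # duplicated omega rows collapse to their mean torque
  p3 <- write_temp_csv(data.frame(omega = c(0.1, 1, 1, 10),
                                  torque = c(1e-5, 2e-5, 4e-5, 9e-5)))
  curve3 <- read_rheometry_csv(p3)
  expect_length(curve3, 3)
  expect_equal(curve3$torque[2], 3e-5)

  expect_error(read_rheometry_csv(write_temp_csv(
    data.frame(speed = 1:3, torque = 1:3))), "'omega'")
  empty <- tempfile(fileext = ".csv"); file.create(empty)
  expect_error(read_rheometry_csv(empty), "empty")
})

test_that("indentation CSV reader ignores extra columns, converts units, trims retraction", {
  d_um <- seq(0, 100, length.out = 30)
  p <- write_temp_csv(data.frame(time = seq_along(d_um),
                                 displacement = d_um, force = d_um * 2))
  curve <- read_indentation_csv(p, displacement_unit = "um", force_unit = "mN")
  expect_equal(curve$displacement, d_um * 1e-6)
  expect_equal(curve$force, d_um * 2e-3)

  # approach of 30 samples then 10 retraction samples: only approach kept
  d <- c(seq(0, 100, length.out = 30), seq(97, 70, length.out = 10))
  p2 <- write_temp_csv(data.frame(displacement = d, force = seq_along(d)))
  curve2 <- read_indentation_csv(p2, displacement_unit = "um")
  expect_length(curve2, 30)
  expect_equal(max(curve2$displacement), 100e-6)

  expect_error(read_indentation_csv(write_temp_csv(
    data.frame(displacement = 1:5, force = 1:5))), "too few samples")
  expect_error(read_indentation_csv(write_temp_csv(
    data.frame(displacement = seq(100, 1, length.out = 20),
               force = 1:20))), "negative displacement span")
})

test_that("curves round-trip through CSV to 1e-12 relative", {
  gen <- generate_torque_curve(cf0 = 0.05, noise_sd = 0.01, seed = 11)
  p <- tempfile(fileext = ".csv")
  write_rheometry_csv(gen$curve, p)
  back <- read_rheometry_csv(p)
  expect_equal(back$omega, gen$curve$omega, tolerance = 1e-12)
  expect_equal(back$torque, gen$curve$torque, tolerance = 1e-12)

  gi <- generate_indentation_curve(E = 10e3, seed = 11)
  p2 <- tempfile(fileext = ".csv")
  write_indentation_csv(gi$curve, p2)
  back2 <- read_indentation_csv(p2)
  expect_equal(back2$displacement, gi$curve$displacement, tolerance = 1e-12)
  expect_equal(back2$force, gi$curve$force, tolerance = 1e-12)
})

test_that("image stacks survive per-channel and interleaved TIFF round trips", {
  gen <- generate_image_stack(shape = c(12, 16, 16), seed = 5)
  stk <- gen$stack
  paths <- c(cells = tempfile(fileext = ".tif"),
             eps = tempfile(fileext = ".tif"))
  write_image_stack(stk, paths)
  back <- read_image_stack(paths, voxel_size = stk$voxel_size)
  expect_equal(dim(back), c(12, 16, 16))
  for (ch in c("cells", "eps"))
    expect_identical(back$channels[[ch]] > 0.5, stk$channels[[ch]])

  # interleaved layout: pages alternate cells/eps
  pages <- list()
  for (z in 1:12) {
    pages[[2 * z - 1]] <- stk$channels$cells[z, , ] * 1.0
    pages[[2 * z]] <- stk$channels$eps[z, , ] * 1.0
  }
  p_int <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, p_int, bits.per.sample = 8L)
  back2 <- read_image_stack(p_int, voxel_size = stk$voxel_size,
                            channel_names = c("cells", "eps"))
  expect_identical(back2$channels$cells > 0.5, stk$channels$cells)
  expect_identical(back2$channels$eps > 0.5, stk$channels$eps)
})

test_that("top-down acquisition flips the z axis so slice 1 is the substratum", {
  # asymmetric slab: occupies only the top two acquired slices
  a <- array(FALSE, dim = c(6, 4, 4))
  a[1:2, , ] <- TRUE   # as acquired, top-down: first slices are biofilm top
  p <- tempfile(fileext = ".tif")
  write_image_stack(image_stack(list(cells = a), c(1, 1, 1)),
                    c(cells = p))
  up <- read_image_stack(c(cells = p), voxel_size = c(1, 1, 1),
                         acquisition = "top-down")
  occ <- apply(up$channels$cells > 0.5, 1, any)
  expect_equal(which(occ), 5:6)   # flipped: occupancy now at the far end
  expect_false(occ[1])
})

test_that("stack validation catches shape mismatches and missing voxel size", {
  a <- array(0, dim = c(3, 4, 4)); b <- array(0, dim = c(3, 4, 5))
  expect_error(image_stack(list(cells = a, eps = b), c(1, 1, 1)),
               "shape mismatch")
  expect_error(image_stack(list(cells = a), c(1, -1, 1)), "voxel_size")
  p1 <- tempfile(fileext = ".tif"); p2 <- tempfile(fileext = ".tif")
  write_image_stack(image_stack(list(cells = a), c(1, 1, 1)), c(cells = p1))
  write_image_stack(image_stack(list(eps = b), c(1, 1, 1)), c(eps = p2))
  expect_error(read_image_stack(c(cells = p1, eps = p2),
                                voxel_size = c(1, 1, 1)), "mismatch")
  expect_error(read_image_stack(c(cells = p1, eps = p2)), "voxel_size")
})
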