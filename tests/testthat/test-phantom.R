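test_that("phantom sphere voxelization matches the analytic volume", {
  spec <- phantom_spec(shape = c(56, 56, 56), spacing = c(0.4, 0.4, 0.4),
                       layers = list(list(center = NULL, semiaxes = 10, base = 100)))
  ph <- generate_phantom(spec)
  vcount <- sum(ph$mask) * 0.4^3
  va <- ph$ground_truth$ellipsoids$volume_mm3[1]
  expect_equal(va, 4 / 3 * pi * 1000)
  expect_lt(abs(vcount / va - 1), 0.01)
  expect_false(ph$ground_truth$ellipsoids$clipped[1])
})

test_that("voxelization error shrinks with grid refinement", {
  err_at <- function(sp) {
    spec <- phantom_spec(shape = rep(ceiling(24 / sp) + 4, 3), spacing = rep(sp, 3),
                         layers = list(list(center = NULL, semiaxes = 10, base = 1)))
    ph <- generate_phantom(spec)
    abs(sum(ph$mask) * sp^3 - 4 / 3 * pi * 1000)
  }
  expect_lt(err_at(0.25), err_at(0.5) * 0.9)
})

test_that("noise-free gradients hit their analytic endpoints", {
  spec <- phantom_spec(shape = c(41, 41, 41), spacing = c(1, 1, 1),
                       layers = list(list(center = c(20, 20, 20), semiaxes = 15,
                                          base = 200)),
                       gradient = list(mode = "radial", span = 600))
  ph <- generate_phantom(spec)
  fn <- ph$ground_truth$intensity_fn
  expect_equal(fn(matrix(c(20, 20, 20), 1)), 200)          # centre = base
  expect_equal(fn(matrix(c(35, 20, 20), 1)), 800)          # surface = base + span
  expect_equal(fn(matrix(c(39, 20, 20), 1)), 0)            # outside = background
  # voxel field matches the analytic function exactly without noise
  expect_equal(ph$vol$voxels[21, 21, 21], 200)
  b <- compute_bounds(ph$vol, ph$mask)
  expect_gte(b["lo"], 200)
  expect_lte(b["hi"], 800)
})

test_that("phantom generation is seed-deterministic", {
  s <- phantom_preset("gradient-sphere", shape = c(48, 48, 48),
                      spacing = c(1, 1, 1), seed = 5)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$vol$voxels, b$vol$voxels)
  s2 <- phantom_preset("gradient-sphere", shape = c(48, 48, 48),
                       spacing = c(1, 1, 1), seed = 6)
  c <- generate_phantom(s2)
  expect_false(identical(a$vol$voxels, c$vol$voxels))
  # masks are geometry-only, identical across seeds
  expect_identical(a$mask, c$mask)
})

test_that("an ellipsoid exceeding the grid is flagged", {
  spec <- phantom_spec(shape = c(10, 10, 10), spacing = c(1, 1, 1),
                       layers = list(list(center = c(5, 5, 5), semiaxes = 20,
                                          base = 1)))
  expect_warning(ph <- generate_phantom(spec), "exceed")
})

test_that("DICOM round trip preserves geometry and quantised intensities", {
  ph <- generate_phantom(phantom_spec(shape = c(12, 10, 6), spacing = c(0.8, 0.8, 3),
    layers = list(list(center = c(4.4, 3.6, 7.5), semiaxes = c(3.5, 3, 6),
                       base = 300)),
    noise_sd = 5, seed = 3))
  d <- tempfile()
  man <- write_phantom_dicom(ph$vol, ph$mask, d)
  # one DICOM per slice plus one mask PNG per slice
  expect_equal(sum(grepl("\\.dcm$", man$file)), 6)
  expect_equal(sum(grepl("\\.png$", man$file)), 6)

  v2 <- read_volume(d)
  expect_equal(v2$spacing, ph$vol$spacing)
  quant <- (max(ph$vol$voxels) - min(ph$vol$voxels)) / 65535
  expect_lt(max(abs(v2$voxels - ph$vol$voxels)), quant)
  m2 <- read_mask(file.path(d, "mask"), v2)
  expect_equal(array(as.logical(m2), dim(m2)),
               array(as.logical(ph$mask), dim(ph$mask)))

  # a single-slice write is rejected by the series reader
  ph1 <- suppressWarnings(generate_phantom(phantom_spec(
    shape = c(6, 6, 1), spacing = c(1, 1, 1),
    layers = list(list(center = c(2.5, 2.5, 0), semiaxes = c(2, 2, 1), base = 10)))))
  d1 <- tempfile()
  write_phantom_dicom(ph1$vol, NULL, d1)
  expect_error(read_volume(d1, format = "dicom_series"), class = "vxp_data_error")
})

test_that("presets build their documented geometries", {
  tb <- phantom_preset("two-blobs", spacing = c(1, 1, 1))
  ph <- generate_phantom(tb)
  expect_equal(length(tb$layers), 2)
  expect_equal(ph$ground_truth$ellipsoids$volume_mm3,
               rep(4 / 3 * pi * 8^3, 2))
  ne <- phantom_preset("nested-ellipsoids", spacing = c(1, 1, 1))
  expect_equal(length(ne$layers), 3)
})
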