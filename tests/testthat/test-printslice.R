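test_that("printer profile derives droplet pitches from DPI", {
  prof <- printer_profile()
  expect_equal(prof$pitch_x, 25.4 / 600)
  expect_equal(prof$pitch_y, 25.4 / 300)
  expect_equal(prof$layer_mm, 0.027)
  expect_error(printer_profile(dpi_x = 0), class = "vxp_config_error")
})

draft_profile <- function(p = c(0.5, 0.5, 0.5)) {
  printer_profile(dpi_x = 25.4 / p[1], dpi_y = 25.4 / p[2], layer_mm = p[3])
}

test_that("reslicing preserves constant fields and matches affine ramps", {
  v <- image_volume(array(0.42, c(10, 10, 10)), c(1, 1, 1))
  m <- as_mask(array(TRUE, c(10, 10, 10)))
  res <- reslice(v, m, draft_profile(c(0.3, 0.4, 0.5)))
  expect_true(all(abs(res$vol$voxels - 0.42) < 1e-12))
  expect_equal(res$vol$spacing, c(0.3, 0.4, 0.5))

  # trilinear interpolation is exact on affine fields (interior samples)
  g <- expand.grid(i = 0:9, j = 0:9, k = 0:9)
  ramp <- array(2 * g$i + 3 * g$j - g$k + 5, c(10, 10, 10))
  vr <- image_volume(ramp, c(1, 1, 1))
  res2 <- reslice(vr, m, draft_profile(c(0.25, 0.25, 0.25)))
  d <- dim(res2$vol$voxels)
  xs <- res2$vol$origin[1] + (seq_len(d[1]) - 1) * res2$vol$spacing[1]
  ys <- res2$vol$origin[2] + (seq_len(d[2]) - 1) * res2$vol$spacing[2]
  zs <- res2$vol$origin[3] + (seq_len(d[3]) - 1) * res2$vol$spacing[3]
  ix <- which(xs >= 0 & xs <= 9); iy <- which(ys >= 0 & ys <= 9)
  iz <- which(zs >= 0 & zs <= 9)
  want <- outer(outer(2 * xs[ix], 3 * ys[iy], "+"), -zs[iz], "+") + 5
  expect_equal(res2$vol$voxels[ix, iy, iz], want, tolerance = 1e-6)

  expect_error(reslice(v, m, printer_profile(dpi_x = 2, dpi_y = 2, layer_mm = 50)),
               class = "vxp_data_error")
})

test_that("output grid dimensions follow ceil(extent / pitch)", {
  v <- image_volume(array(1, c(20, 20, 8)), c(1, 1, 2.5))
  m <- as_mask(array(TRUE, c(20, 20, 8)))
  res <- reslice(v, m, draft_profile(c(0.7, 0.9, 0.6)))
  expect_equal(dim(res$vol$voxels),
               c(ceiling(20 / 0.7), ceiling(20 / 0.9), ceiling(20 / 0.6)))
})

test_that("colorized slices equal the LUT evaluated pointwise, transparent off-mask", {
  set.seed(61)
  v <- image_volume(array(runif(12 * 11 * 5), c(12, 11, 5)), c(1, 1, 1))
  m <- array(TRUE, c(12, 11, 5))
  m[, , 3] <- FALSE          # one fully masked-out layer
  m[1:4, , ] <- FALSE
  res <- reslice(v, as_mask(m), draft_profile(c(1, 1, 1)))
  lut <- color_lut(partition_range(0, 1, 4), blend_mode = "linear")
  stack <- colorize_stack(res, lut)
  for (k in seq_along(stack$slices)) {
    want <- lut_color(as.vector(res$vol$voxels[, , k]), lut)
    want[!as.vector(res$mask[, , k]), ] <- 0
    want <- round(want * 255) / 255
    expect_equal(as.vector(stack$slices[[k]]), as.vector(want))
  }
  # the masked-out layer is fully transparent
  koff <- which(vapply(seq_along(stack$slices),
                       function(k) !any(res$mask[, , k]), TRUE))
  expect_true(length(koff) >= 1)
  expect_true(all(stack$slices[[koff[1]]][, , 4] == 0))

  # single-division LUT paints every masked pixel the same colour
  lut1 <- color_lut(partition_range(0, 1, 1), colors = "#AA3377")
  s1 <- colorize_stack(res, lut1)
  on_px <- s1$slices[[1]][, , 4] > 0
  for (c in 1:3) {
    expect_equal(length(unique(s1$slices[[1]][, , c][on_px])), 1)
  }
})

test_that("PNG stack writes z-ordered numbered files that read back exactly", {
  set.seed(62)
  v <- image_volume(array(runif(8 * 8 * 10), c(8, 8, 10)), c(1, 1, 1))
  m <- as_mask(array(runif(640) > 0.3, c(8, 8, 10)))
  res <- reslice(v, m, draft_profile(c(1, 1, 1)))
  stack <- colorize_stack(res, color_lut(partition_range(0, 1, 2)))
  d <- tempfile()
  man <- write_png_stack(stack, d)
  expect_equal(man$file, sprintf("slice_%04d.png", seq_along(stack$slices) - 1))
  expect_equal(attr(man, "total_bytes"), sum(man$bytes))
  back <- read_png_stack(d)
  expect_equal(back$slices, stack$slices, tolerance = 1e-9)
  expect_equal(back$pitch, stack$pitch)
  expect_equal(back$layer_mm, stack$layer_mm)
})

test_that("alpha-carrying pixel count conserves the masked physical volume", {
  ph <- generate_phantom(phantom_preset("gradient-sphere", seed = 3,
                                        shape = c(40, 40, 16),
                                        spacing = c(1.2, 1.2, 3)))
  wvol <- apply_window_level(ph$vol, window_level(400, 900))
  res <- reslice(wvol, ph$mask, draft_profile(c(0.6, 0.6, 0.75)))
  stack <- colorize_stack(res, color_lut(partition_range(0, 1, 4)))
  src <- sum(ph$mask) * prod(ph$vol$spacing)
  expect_lt(abs(stack_volume_mm3(stack) / src - 1), 0.01)
})
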