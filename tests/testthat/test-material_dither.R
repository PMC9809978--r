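bw_palette <- function() material_palette(c("black", "white"), c("#000000", "#FFFFFF"))

test_that("palette validation enforces K >= 2 and distinct colours", {
  expect_error(material_palette("one", "#FFFFFF"), class = "vxp_config_error")
  expect_error(material_palette(c("a", "b"), c("#FFFFFF", "#FFFFFF")),
               class = "vxp_config_error")
  expect_warning(material_palette(letters[1:7],
                                  c("#000000", "#111111", "#222222", "#333333",
                                    "#444444", "#555555", "#666666")),
                 "six")
})

test_that("an image of exact palette colours is a fixed point of dithering", {
  pal <- default_material_palette()
  for (j in c(1, 4, 6)) {
    img <- array(0, c(16, 16, 4))
    for (c in 1:4) img[, , c] <- pal$rgba[j, c]
    img[, , 4] <- 1
    expect_true(all(dither_slice(img, pal) == j))
  }
})

test_that("50 percent gray dithers to half white, half black", {
  img <- array(0, c(64, 64, 4))
  img[, , 1:3] <- 1.055 * 0.5^(1 / 2.4) - 0.055   # linear-light 0.5
  img[, , 4] <- 1
  d <- dither_slice(img, bw_palette())
  expect_lt(abs(mean(d == 2) - 0.5), 0.01)
})

test_that("the first pixels of a mid-gray row follow the tie-break and diffusion rule", {
  # 1 x 2 row at linear 0.5, palette {black, white}: the tie at the first
  # pixel goes to the lowest index (black), pushing +0.5 * 7/16 ahead, so
  # the second pixel (0.71875) quantises to white.
  img <- array(0, c(2, 1, 4))
  img[, , 1:3] <- 1.055 * 0.5^(1 / 2.4) - 0.055
  img[, , 4] <- 1
  expect_identical(as.vector(dither_slice(img, bw_palette())), c(1L, 2L))
})

test_that("a 2x2 mid-gray block matches the hand-traced serpentine recurrence", {
  # Hand trace (linear values, palette black = 0, white = 1):
  #  (1,1): 0.5 -> tie -> black, error +0.5: right +7/16, below +5/16,
  #         below-right +1/16
  #  (2,1): 0.5 + 0.21875 = 0.71875 -> white, error -0.28125:
  #         below-left 3/16, below 5/16
  #  row 2 scans right-to-left:
  #  (2,2): 0.5 + 0.03125 - 0.087890625 = 0.443359375 -> black
  #         error +0.443359375 -> "ahead" is (1,2): +7/16
  #  (1,2): 0.5 + 0.15625 - 0.052734375 + 0.193969726... = 0.797485... -> white
  img <- array(0, c(2, 2, 4))
  img[, , 1:3] <- 1.055 * 0.5^(1 / 2.4) - 0.055
  img[, , 4] <- 1
  want <- matrix(c(1L, 2L,   # x = 1..2 at y = 1
                   2L, 1L),  # x = 1..2 at y = 2
                 nrow = 2)
  expect_identical(dither_slice(img, bw_palette()), want)
})

test_that("dithering matches the independent plain-loop recurrence bit-exactly", {
  pal <- default_material_palette()
  for (seed in 1:4) {
    set.seed(seed)
    img <- array(runif(16 * 12 * 4), c(16, 12, 4))
    img[, , 4] <- ifelse(img[, , 4] > 0.2, 1, 0)   # irregular mask
    expect_identical(dither_slice(img, pal), oracle_dither(img, pal))
  }
  # and for the 4x4 case with a 2-material palette
  set.seed(9)
  img <- array(runif(4 * 4 * 4), c(4, 4, 4))
  img[, , 4] <- 1
  expect_identical(dither_slice(img, bw_palette()), oracle_dither(img, bw_palette()))
})

test_that("sentinel pixels coincide exactly with alpha-0 pixels", {
  set.seed(71)
  img <- array(runif(32 * 32 * 4), c(32, 32, 4))
  img[, , 4] <- ifelse(img[, , 4] > 0.5, 1, 0)
  d <- dither_slice(img, default_material_palette())
  expect_identical(d == 0L, img[, , 4] == 0)
})

test_that("dithering is deterministic", {
  set.seed(72)
  img <- array(runif(20 * 20 * 4), c(20, 20, 4))
  img[, , 4] <- 1
  pal <- default_material_palette()
  expect_identical(dither_slice(img, pal), dither_slice(img, pal))
})

stack_from_slices <- function(slices, pal) {
  structure(list(slices = slices, palette = pal, pitch = c(0.5, 0.5),
                 layer_mm = 0.5, z_mm = (seq_along(slices) - 1) * 0.5,
                 origin_xy = c(0, 0)),
            class = "material_slice_stack")
}

test_that("material fractions recover mixtures and add over partitions", {
  palcw <- material_palette(c("cyan", "white"), c("#00FFFF", "#FFFFFF"))
  img <- mixture_image(c(0.3, 0.7), palcw, 128, 128)
  d <- dither_slice(img, palcw)
  st <- stack_from_slices(list(d), palcw)
  fr <- material_fractions(st)
  expect_equal(fr$fraction, c(0.3, 0.7), tolerance = 0.01)
  expect_equal(sum(fr$fraction), 1)

  # additivity: region fractions recombine into whole-stack fractions
  left <- array(FALSE, c(128, 128, 1)); left[1:64, , ] <- TRUE
  right <- !left
  fl <- material_fractions(st, left)
  fr2 <- material_fractions(st, right)
  nl <- sum(fl$count); nr <- sum(fr2$count)
  expect_equal((fl$fraction * nl + fr2$fraction * nr) / (nl + nr), fr$fraction)

  # pure region
  pure <- stack_from_slices(list(matrix(1L, 8, 8)), palcw)
  expect_equal(material_fractions(pure)$fraction, c(1, 0))

  empty <- stack_from_slices(list(matrix(0L, 8, 8)), palcw)
  expect_error(material_fractions(empty), class = "vxp_empty_region")
})

test_that("material stacks round-trip through both on-disk layouts", {
  pal <- default_material_palette()
  set.seed(81)
  slices <- lapply(1:3, function(k) {
    m <- matrix(sample(0:6, 24 * 18, replace = TRUE), 24, 18)
    storage.mode(m) <- "integer"
    m
  })
  st <- stack_from_slices(slices, pal)
  d1 <- tempfile(); d2 <- tempfile()
  write_material_stack(st, d1, mode = "indexed_png")
  write_material_stack(st, d2, mode = "per_material_bitmaps")
  b1 <- read_material_stack(d1)
  b2 <- read_material_stack(d2)
  expect_identical(b1$slices, st$slices)
  expect_identical(b2$slices, st$slices)
  expect_equal(b1$palette$names, pal$names)

  # per-material bitmaps are complementary for a 2-material checkerboard
  chk <- matrix(rep_len(c(1L, 2L), 16 * 16), 16, 16)
  stc <- stack_from_slices(list(chk), bw_palette())
  d3 <- tempfile()
  write_material_stack(stc, d3, mode = "per_material_bitmaps")
  m1 <- png::readPNG(file.path(d3, "slice_0000_m1.png")) > 0.5
  m2 <- png::readPNG(file.path(d3, "slice_0000_m2.png")) > 0.5
  expect_true(all(xor(m1, m2)))
  # OR-reduction over channels equals the material-present mask
  expect_true(all(m1 | m2))
})
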