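# Independent oracles and fixture builders. These re-derive expected values
# by plain enumeration/recurrence so they stay independent of the package's
# implementation paths.

# sRGB decoding written out independently of the package's helper.
oracle_srgb_decode <- function(v) {
  out <- v
  small <- v <= 0.04045
  out[small] <- v[small] / 12.92
  out[!small] <- ((v[!small] + 0.055) / 1.055)^2.4
  out
}

# Plain-loop Floyd-Steinberg recurrence: serpentine rows (row index = second
# array dimension), weights 7/16 ahead, 3/16 behind-below, 5/16 below, 1/16
# ahead-below, error clamped to [-1, 1] per channel before the nearest-
# palette search, ties to the lowest index, alpha-0 pixels skipped entirely.
oracle_dither <- function(img, palette) {
  nx <- dim(img)[1]
  ny <- dim(img)[2]
  lin <- oracle_srgb_decode(img[, , 1:3, drop = FALSE])
  alive <- img[, , 4] > 0
  pal <- oracle_srgb_decode(palette$rgba[, 1:3, drop = FALSE])
  k <- nrow(pal)
  err <- array(0, c(nx, ny, 3))
  out <- matrix(0L, nx, ny)
  for (y in seq_len(ny)) {
    dir <- if (y %% 2 == 1) 1L else -1L
    xs <- if (dir == 1L) seq_len(nx) else rev(seq_len(nx))
    for (x in xs) {
      if (!alive[x, y]) next
      e <- pmin(pmax(err[x, y, ], -1), 1)
      cadj <- lin[x, y, ] + e
      d2 <- colSums((t(pal) - cadj)^2)
      best <- which.min(d2)  # which.min takes the first (lowest index) tie
      out[x, y] <- best
      q <- cadj - pal[best, ]
      targets <- list(c(x + dir, y, 7), c(x - dir, y + 1, 3),
                      c(x, y + 1, 5), c(x + dir, y + 1, 1))
      for (tg in targets) {
        xx <- tg[1]; yy <- tg[2]
        if (xx < 1 || xx > nx || yy < 1 || yy > ny) next
        if (!alive[xx, yy]) next
        err[xx, yy, ] <- err[xx, yy, ] + q * tg[3] / 16
      }
    }
  }
  out
}

# Logical array of a digitized sphere sampled at voxel centres.
digitized_sphere <- function(radius, sp, margin = 2) {
  n <- as.integer(ceiling(2 * radius / sp)) + 2L * margin + 1L
  cc <- (n - 1) * sp / 2
  xs <- (seq_len(n) - 1) * sp
  dx2 <- outer(xs - cc, rep(1, n))^2
  arr <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) {
    arr[, , k] <- dx2 + t(dx2) + (xs[k] - cc)^2 <= radius^2
  }
  arr
}

# Hand-built unit cube: 8 vertices at 0/1 coordinates, 12 consistently
# outward-oriented triangles.
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0, normal -z
    c(5, 6, 7), c(6, 8, 7),   # z = 1, normal +z
    c(1, 2, 5), c(2, 6, 5),   # y = 0, normal -y
    c(3, 7, 4), c(4, 7, 8),   # y = 1, normal +y
    c(1, 5, 3), c(3, 5, 7),   # x = 0, normal -x
    c(2, 4, 6), c(4, 8, 6)    # x = 1, normal +x
  )
  voxelprint:::new_mesh(v, f)
}

# Uniform RGBA image whose colour is a linear-light convex mixture of
# palette entries.
mixture_image <- function(weights, palette, nx = 128, ny = 128) {
  pal_lin <- oracle_srgb_decode(palette$rgba[, 1:3, drop = FALSE])
  target <- colSums(weights * pal_lin)
  srgb <- ifelse(target <= 0.0031308, 12.92 * target,
                 1.055 * pmin(pmax(target, 0), 1)^(1 / 2.4) - 0.055)
  img <- array(0, c(nx, ny, 4))
  for (c in 1:3) img[, , c] <- srgb[c]
  img[, , 4] <- 1
  img
}

# Palette pairs for which no third material is ever the nearest point along
# the mixing segment (computed from palette geometry): for these, fraction
# recovery from dithered output is well-posed.
clean_palette_pairs <- function(palette) {
  pl <- oracle_srgb_decode(palette$rgba[, 1:3, drop = FALSE])
  k <- nrow(pl)
  pairs <- t(utils::combn(k, 2))
  keep <- apply(pairs, 1, function(r) {
    for (f in seq(0.02, 0.98, by = 0.02)) {
      p <- f * pl[r[1], ] + (1 - f) * pl[r[2], ]
      d <- colSums((t(pl) - p)^2)
      if (!(which.min(d) %in% r)) return(FALSE)
    }
    TRUE
  })
  pairs[keep, , drop = FALSE]
}

# Shared expensive fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Comparison study on the gradient-sphere phantom at a draft printer grid
# (0.4 x 0.4 x 0.5 mm) — shared by the trend checks.
gradient_sphere_report <- function() {
  fixture("gradient_sphere_report", function() {
    ph <- generate_phantom(phantom_preset("gradient-sphere", seed = 17))
    wvol <- apply_window_level(ph$vol, window_level(
      center = mean(compute_bounds(ph$vol, ph$mask)),
      width = diff(range(compute_bounds(ph$vol, ph$mask)))))
    prof <- printer_profile(dpi_x = 25.4 / 0.4, dpi_y = 25.4 / 0.4,
                            layer_mm = 0.5)
    run_comparison(wvol, ph$mask, division_counts = c(2, 4, 10),
                   profile = prof, out_dir = file.path(tempdir(), "gs_report"))
  })
}
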