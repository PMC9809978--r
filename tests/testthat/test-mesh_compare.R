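label_map_from <- function(ind, spacing = c(1, 1, 1)) {
  labels <- array(NA_integer_, dim(ind))
  labels[ind] <- 1L
  structure(list(labels = labels, n_divisions = 1L, spacing = spacing,
                 origin = c(0, 0, 0)), class = "label_map")
}

test_that("label maps agree with a per-voxel brute-force threshold scan", {
  set.seed(91)
  v <- image_volume(array(runif(8 * 7 * 6, 10, 50), c(8, 7, 6)), c(1, 1, 1))
  m <- as_mask(array(runif(336) > 0.3, c(8, 7, 6)))
  b <- compute_bounds(v, m)
  p <- partition_range(b["lo"], b["hi"], 5)
  lm <- build_label_map(v, m, p)

  # single division reproduces the mask
  p1 <- partition_range(b["lo"], b["hi"], 1)
  lm1 <- build_label_map(v, m, p1)
  expect_identical(!is.na(lm1$labels), array(as.logical(m), dim(m)))

  # label histogram covers every masked voxel exactly once
  expect_equal(sum(table(lm$labels)), sum(m))

  # brute-force: each masked voxel labelled by scanning division ranges
  for (i in seq_len(dim(m)[1])) for (j in seq_len(dim(m)[2])) for (k in seq_len(dim(m)[3])) {
    if (!m[i, j, k]) {
      expect_true(is.na(lm$labels[i, j, k]))
    } else {
      val <- v$voxels[i, j, k]
      want <- NA_integer_
      for (dd in 1:5) {
        if (val >= p$edges[dd] && (val < p$edges[dd + 1] || dd == 5)) {
          want <- dd
          break
        }
      }
      expect_identical(lm$labels[i, j, k], want)
    }
  }

  # partition not derived from these bounds is rejected
  bad <- partition_range(b["lo"] + 5, b["hi"], 3)
  expect_error(build_label_map(v, m, bad), class = "vxp_data_error")
})

test_that("extracted surfaces are watertight with voxel-accurate volume", {
  # solid 10x10x10 voxel cube at 1 mm: volume within the half-voxel
  # surface-shell band around 1000 mm^3
  lm <- label_map_from(array(TRUE, c(10, 10, 10)))
  m <- extract_mesh(lm, 1)
  expect_true(is_watertight(m))
  vol <- mesh_volume(m)
  shell <- 600 * 0.5
  expect_gt(vol, 1000 - shell)
  expect_lt(vol, 1000 + shell)
  expect_equal(count_components(m), 1)

  # a single isolated voxel is one closed component
  ind <- array(FALSE, c(5, 5, 5)); ind[3, 3, 3] <- TRUE
  m1 <- extract_mesh(label_map_from(ind), 1)
  expect_true(is_watertight(m1))
  expect_equal(count_components(m1), 1)

  # two disjoint blobs stay two components
  ind2 <- array(FALSE, c(12, 6, 6))
  ind2[2:4, 2:4, 2:4] <- TRUE
  ind2[8:11, 2:5, 2:5] <- TRUE
  m2 <- extract_mesh(label_map_from(ind2), 1)
  expect_equal(count_components(m2), 2)

  # empty division signals an empty mesh
  lm0 <- label_map_from(array(FALSE, c(3, 3, 3)))
  lm0$labels[1, 1, 1] <- 2L   # only another division present
  lm0$n_divisions <- 2L
  expect_warning(m0 <- extract_mesh(lm0, 1), "no voxels")
  expect_equal(nrow(m0$faces), 0)
})

test_that("digitized sphere volume matches the analytic and voxel-count oracles", {
  sp <- 0.5
  ind <- digitized_sphere(8, sp)
  vcount <- sum(ind) * sp^3
  m <- extract_mesh(label_map_from(ind, rep(sp, 3)), 1)
  vol <- mesh_volume(m)
  expect_lt(abs(vol / (4 / 3 * pi * 8^3) - 1), 0.02)
  expect_lt(abs(vol / vcount - 1), 0.01)
})

test_that("enclosed volume is exact on the unit cube and translation-invariant", {
  cube <- unit_cube_mesh()
  expect_equal(mesh_volume(cube), 1)
  shifted <- cube
  shifted$vertices <- cube$vertices +
    matrix(c(12.3, -4.5, 99), nrow(cube$vertices), 3, byrow = TRUE)
  expect_equal(mesh_volume(shifted), 1, tolerance = 1e-12)

  # an open mesh is reported, not silently integrated
  holed <- cube
  holed$faces <- holed$faces[-1, ]
  expect_error(mesh_volume(holed), "watertight", class = "vxp_data_error")
})

test_that("component counting matches constructions and ignores ordering", {
  # k isolated voxels meshed together -> k components
  set.seed(101)
  ind <- array(FALSE, c(14, 14, 14))
  picks <- cbind(c(2, 5, 8, 11, 13), c(3, 7, 11, 2, 13), c(2, 6, 10, 12, 4))
  ind[picks] <- TRUE
  m <- extract_mesh(label_map_from(ind), 1)
  expect_equal(count_components(m), 5)

  # two cubes concatenated into one STL file
  c1 <- unit_cube_mesh()
  c2 <- unit_cube_mesh()
  c2$vertices <- c2$vertices + 5
  f <- tempfile(fileext = ".stl")
  write_stl(list(c1, c2), f)
  both <- read_stl(f)
  expect_equal(count_components(both), 2)
  expect_equal(mesh_volume(both), 2, tolerance = 1e-6)

  # invariance under face reordering and vertex renumbering
  perm_f <- sample(nrow(m$faces))
  m_shuf <- m
  m_shuf$faces <- m$faces[perm_f, ]
  expect_equal(count_components(m_shuf), count_components(m))
  perm_v <- sample(nrow(m$vertices))
  inv <- integer(length(perm_v)); inv[perm_v] <- seq_along(perm_v)
  m_ren <- m
  m_ren$vertices <- m$vertices[perm_v, ]
  m_ren$faces <- matrix(inv[m$faces], ncol = 3)
  expect_equal(count_components(m_ren), count_components(m))
  expect_equal(mesh_volume(m_ren), mesh_volume(m), tolerance = 1e-12)
})

test_that("binary STL round-trips triangle count and volume to float precision", {
  ind <- digitized_sphere(4, 0.8)
  m <- extract_mesh(label_map_from(ind, rep(0.8, 3)), 1)
  f <- tempfile(fileext = ".stl")
  write_stl(m, f)
  expect_equal(file.size(f), 84 + 50 * nrow(m$faces))
  back <- read_stl(f)
  expect_equal(nrow(back$faces), nrow(m$faces))
  expect_equal(mesh_volume(back), mesh_volume(m), tolerance = 1e-6)
})

test_that("mesh metrics summarise counts, volume, components and file bytes", {
  cube <- unit_cube_mesh()
  mm <- mesh_metrics(cube, file_bytes = 684)
  expect_equal(mm$n_faces, 12)
  expect_equal(mm$n_vertices, 8)
  expect_equal(mm$enclosed_volume, 1)
  expect_equal(mm$n_components, 1)
  expect_equal(mm$file_bytes, 684)
})

test_that("comparison on a constant phantom yields one populated division", {
  v <- image_volume(array(5, c(16, 16, 8)), c(1, 1, 1))
  msk <- array(FALSE, c(16, 16, 8)); msk[4:13, 4:13, 2:7] <- TRUE
  wv <- apply_window_level(v, window_level(5, 2))
  rep <- suppressWarnings(run_comparison(wv, as_mask(msk), division_counts = 2,
                          profile = printer_profile(dpi_x = 25.4 / 0.5,
                                                    dpi_y = 25.4 / 0.5,
                                                    layer_mm = 0.5),
                          out_dir = tempfile()))
  td <- tidy(rep)
  expect_equal(sum(td$n_faces > 0), 1)   # only one nonempty division
  src <- sum(msk) * 1
  expect_lt(abs(sum(td$enclosed_volume) / src - 1), 0.10)
  expect_lt(abs(glance(rep)$voxel_volume_mm3 / src - 1), 0.01)
})
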