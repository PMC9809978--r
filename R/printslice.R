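#' Printer profile: native resolutions and material palette
#'
#' Defaults follow a six-material PolyJet machine (Stratasys J750 class):
#' 600 DPI along x, 300 DPI along y — droplet pitches 25.4/600 ~ 0.0423 mm
#' and 25.4/300 ~ 0.0847 mm — and a 0.027 mm layer. Layer thickness is a
#' print-mode parameter (15/27/30 um modes exist); 0.027 mm is the default.
#'
#' @param dpi_x,dpi_y In-plane print resolutions, dots per inch.
#' @param layer_mm Layer thickness in mm.
#' @param palette A [material_palette()]; default the six-material set.
#' @return A `printer_profile` with derived `pitch_x`/`pitch_y` in mm.
#' @export
printer_profile <- function(dpi_x = 600, dpi_y = 300, layer_mm = 0.027,
                            palette = default_material_palette()) {
  if (!is.numeric(dpi_x) || dpi_x <= 0 || !is.numeric(dpi_y) || dpi_y <= 0) {
    stop_config("dpi_x and dpi_y must be positive")
  }
  if (!is.numeric(layer_mm) || layer_mm <= 0) {
    stop_config("layer_mm must be positive")
  }
  structure(list(dpi_x = dpi_x, dpi_y = dpi_y, layer_mm = layer_mm,
                 pitch_x = 25.4 / dpi_x, pitch_y = 25.4 / dpi_y,
                 palette = palette),
            class = "printer_profile")
}

#' @export
print.printer_profile <- function(x, ...) {
  cat(sprintf("<printer_profile> %g x %g DPI (pitch %.4g x %.4g mm), layer %g mm, %d materials\n",
              x$dpi_x, x$dpi_y, x$pitch_x, x$pitch_y, x$layer_mm,
              nrow(x$palette$rgba)))
  invisible(x)
}

# Trilinear interpolation of `vol` at the grid spanned by centre coordinate
# vectors xs, ys, zs (mm). Constant extrapolation beyond the source grid.
# Processes one output slice at a time to bound memory.
trilinear_sample <- function(vol, xs, ys, zs) {
  d <- dim(vol$voxels)
  fx <- (xs - vol$origin[1]) / vol$spacing[1] + 1
  fy <- (ys - vol$origin[2]) / vol$spacing[2] + 1
  fz <- (zs - vol$origin[3]) / vol$spacing[3] + 1
  i0 <- pmin(pmax(floor(fx), 1), max(d[1] - 1, 1)); wx <- pmin(pmax(fx - i0, 0), 1)
  j0 <- pmin(pmax(floor(fy), 1), max(d[2] - 1, 1)); wy <- pmin(pmax(fy - j0, 0), 1)
  k0 <- pmin(pmax(floor(fz), 1), max(d[3] - 1, 1)); wz <- pmin(pmax(fz - k0, 0), 1)
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  nxo <- length(xs); nyo <- length(ys)
  I0 <- rep(i0, times = nyo); I1 <- rep(i1, times = nyo)
  J0 <- rep(j0, each = nxo); J1 <- rep(j1, each = nxo)
  WX <- rep(wx, times = nyo); WY <- rep(wy, each = nxo)
  out <- array(0, c(nxo, nyo, length(zs)))
  for (k in seq_along(zs)) {
    s0 <- vol$voxels[, , k0[k]]
    s1 <- vol$voxels[, , k1[k]]
    bil <- function(s) {
      (1 - WX) * ((1 - WY) * s[cbind(I0, J0)] + WY * s[cbind(I0, J1)]) +
        WX * ((1 - WY) * s[cbind(I1, J0)] + WY * s[cbind(I1, J1)])
    }
    out[, , k] <- (1 - wz[k]) * bil(s0) + wz[k] * bil(s1)
  }
  out
}

# Nearest-neighbour resampling for masks at the same grid.
nearest_sample <- function(mask, spacing, origin, xs, ys, zs) {
  d <- dim(mask)
  ri <- pmin(pmax(round((xs - origin[1]) / spacing[1] + 1), 1), d[1])
  rj <- pmin(pmax(round((ys - origin[2]) / spacing[2] + 1), 1), d[2])
  rk <- pmin(pmax(round((zs - origin[3]) / spacing[3] + 1), 1), d[3])
  mask[ri, rj, rk, drop = FALSE]
}

#' Resample a volume and mask onto the printer's native grid
#'
#' The output grid covers the masked bounding box with one grid cell per
#' printer droplet position: per-axis dimensions `ceil(extent / pitch)`,
#' voxel pitch `(pitch_x, pitch_y, layer_mm)`. Scalar values are obtained by
#' trilinear interpolation (exact on affine fields), the mask by
#' nearest-neighbour.
#'
#' @param vol An [image_volume()] (typically in the working `[0, 1]` domain).
#' @param mask Logical mask congruent with `vol`.
#' @param profile A [printer_profile()].
#' @return List with `vol` (resampled [image_volume()]) and `mask`.
#' @export
reslice <- function(vol, mask, profile) {
  mask <- as_mask(mask, vol)
  if (!any(mask)) stop_data("mask selects no voxels; nothing to reslice")
  idx <- which(mask, arr.ind = TRUE)
  lo_idx <- apply(idx, 2, min)
  hi_idx <- apply(idx, 2, max)
  # physical bounding box of the masked voxels, treating voxels as cells
  box_lo <- vol$origin + (lo_idx - 1) * vol$spacing - vol$spacing / 2
  box_hi <- vol$origin + (hi_idx - 1) * vol$spacing + vol$spacing / 2
  extent <- box_hi - box_lo
  pitch <- c(profile$pitch_x, profile$pitch_y, profile$layer_mm)
  if (any(extent < pitch)) {
    stop_data("masked extent (", paste(signif(extent, 4), collapse = " x "),
              " mm) is smaller than one output voxel (",
              paste(signif(pitch, 4), collapse = " x "), " mm) in some axis")
  }
  dims <- pmax(ceiling(extent / pitch - 1e-9), 1)
  xs <- box_lo[1] + (seq_len(dims[1]) - 0.5) * pitch[1]
  ys <- box_lo[2] + (seq_len(dims[2]) - 0.5) * pitch[2]
  zs <- box_lo[3] + (seq_len(dims[3]) - 0.5) * pitch[3]
  rvol <- image_volume(trilinear_sample(vol, xs, ys, zs), spacing = pitch,
                       origin = c(xs[1], ys[1], zs[1]))
  rmask <- as_mask(nearest_sample(mask, vol$spacing, vol$origin, xs, ys, zs))
  list(vol = rvol, mask = rmask)
}

#' Apply a colour LUT to a resampled volume, producing the colour slice stack
#'
#' Each output pixel is `lut_color` of its scalar value where the mask is
#' true and fully transparent elsewhere; one RGBA image per z layer, channels
#' quantised to 8 bits.
#'
#' @param resampled List `(vol, mask)` from [reslice()].
#' @param lut A [color_lut()].
#' @return A `color_slice_stack`: list of `nx x ny x 4` arrays plus geometry.
#' @export
colorize_stack <- function(resampled, lut) {
  vol <- resampled$vol
  mask <- resampled$mask
  d <- dim(vol$voxels)
  slices <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    cols <- lut_color(as.vector(vol$voxels[, , k]), lut)
    cols[!as.vector(mask[, , k]), ] <- 0
    slices[[k]] <- array(round(cols * 255) / 255, c(d[1], d[2], 4))
  }
  structure(list(
    slices = slices,
    pitch = vol$spacing[1:2],
    layer_mm = vol$spacing[3],
    z_mm = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3],
    origin_xy = vol$origin[1:2],
    provenance = list(lut_divisions = lut$partition$n_divisions,
                      blend_mode = lut$blend_mode)
  ), class = "color_slice_stack")
}

#' @export
print.color_slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<color_slice_stack> %d layers of %d x %d px, pitch %.4g x %.4g mm, layer %g mm\n",
              length(x$slices), d[1], d[2], x$pitch[1], x$pitch[2], x$layer_mm))
  invisible(x)
}

#' Write a colour slice stack as numbered RGBA PNG files
#'
#' One 8-bit RGBA PNG per layer, named `slice_0000.png` onward in z order,
#' plus a `manifest.json` recording pitches, layer count and byte totals:
#' both on-disk (deflate-compressed) bytes and the uncompressed raster
#' payload (`layers * nx * ny * 4`), the memory the printer must allocate.
#' The payload is governed entirely by raster dimensions, so it is invariant
#' to the number of intensity divisions; compressed on-disk size additionally
#' depends on image entropy.
#'
#' @param stack A [colorize_stack()] result.
#' @param dir Output directory (created if missing).
#' @return A tibble manifest (file, bytes) with attribute `total_bytes`.
#' @export
write_png_stack <- function(stack, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop_io("cannot create directory ", dir)
  }
  files <- character(length(stack$slices))
  for (k in seq_along(stack$slices)) {
    f <- file.path(dir, sprintf("slice_%04d.png", k - 1L))
    # PNG rows are y, columns are x
    img <- aperm(stack$slices[[k]], c(2, 1, 3))
    ok <- tryCatch({png::writePNG(img, f); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop_io("failed to write ", f)
    files[k] <- f
  }
  bytes <- file.size(files)
  d <- dim(stack$slices[[1]])
  payload <- length(files) * d[1] * d[2] * 4
  man <- tibble::tibble(file = basename(files), bytes = bytes)
  meta <- list(kind = "color_slice_stack", layers = length(files),
               pitch_x_mm = stack$pitch[1], pitch_y_mm = stack$pitch[2],
               layer_mm = stack$layer_mm, z0_mm = stack$z_mm[1],
               origin_xy_mm = stack$origin_xy,
               total_bytes = sum(bytes),
               raster_payload_bytes = payload, files = man$file)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(man, "total_bytes") <- sum(bytes)
  attr(man, "raster_payload_bytes") <- payload
  man
}

#' Read back a PNG slice stack written by [write_png_stack()]
#'
#' @param dir Directory containing the slices and `manifest.json`.
#' @return A `color_slice_stack`.
#' @export
read_png_stack <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_io("no manifest.json in ", dir)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  slices <- lapply(file.path(dir, meta$files), function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 4), c(dim(img), 4))
    aperm(img, c(2, 1, 3))
  })
  structure(list(
    slices = slices,
    pitch = c(meta$pitch_x_mm, meta$pitch_y_mm),
    layer_mm = meta$layer_mm,
    z_mm = meta$z0_mm + (seq_along(slices) - 1) * meta$layer_mm,
    origin_xy = as.numeric(meta$origin_xy_mm),
    provenance = list()
  ), class = "color_slice_stack")
}

#' Physical volume carried by a colour slice stack
#'
#' Counts pixels with alpha > 0 and multiplies by the droplet volume
#' `pitch_x * pitch_y * layer_mm`. For smooth masks this conserves the masked
#' source volume — the voxel pipeline's key fidelity property.
#'
#' @param stack A `color_slice_stack`.
#' @return Volume in mm^3.
#' @export
stack_volume_mm3 <- function(stack) {
  npix <- sum(vapply(stack$slices, function(s) sum(s[, , 4] > 0), 0))
  npix * stack$pitch[1] * stack$pitch[2] * stack$layer_mm
}
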