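#' Printable material palette
#'
#' The set of resins loaded in the printer, at most six for the target
#' machine. Each material has a name, an RGBA colour (nominal sRGB — resin
#' colour coordinates are proprietary) and a clear/opaque flag. Colours must
#' be pairwise distinct; the clear resin participates in dithering as an
#' ordinary palette entry with its configured colour.
#'
#' @param names Character vector of material names (length K >= 2).
#' @param colors Hex strings or K x 3/4 matrix of channel values in `[0, 1]`.
#' @param clear Logical vector, `TRUE` for transparent resins. Default all
#'   opaque.
#' @return A `material_palette` object.
#' @export
material_palette <- function(names, colors, clear = NULL) {
  rgba <- as_rgba_matrix(colors)
  k <- nrow(rgba)
  if (k < 2L) stop_config("a material palette needs at least 2 materials")
  if (k > 6L) warning("palette has ", k,
                      " materials; the target printer is limited to six")
  if (length(names) != k) stop_config("need one name per material")
  if (anyDuplicated(rgba[, 1:3, drop = FALSE])) {
    stop_config("material colors must be pairwise distinct")
  }
  clear <- clear %||% rep(FALSE, k)
  structure(list(names = as.character(names), rgba = rgba,
                 clear = as.logical(clear)),
            class = "material_palette")
}

#' Default six-material palette
#'
#' Cyan, magenta, yellow, black, white and clear — the resin set of the
#' six-material PolyJet workflow. Nominal sRGB coordinates; the clear resin
#' is given a neutral light-gray stand-in colour, separated from white so
#' the two remain distinguishable targets for error diffusion.
#'
#' @return A [material_palette()] with 6 entries.
#' @export
default_material_palette <- function() {
  material_palette(
    names = c("cyan", "magenta", "yellow", "black", "white", "clear"),
    colors = c("#00FFFF", "#FF00FF", "#FFFF00", "#000000", "#FFFFFF", "#D9D9D9"),
    clear = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' @export
print.material_palette <- function(x, ...) {
  cat(sprintf("<material_palette> %d materials: %s\n", length(x$names),
              paste0(x$names, ifelse(x$clear, " (clear)", ""), collapse = ", ")))
  invisible(x)
}

#' Read a material palette from a YAML/JSON config file
#'
#' Expected structure: a list of materials, each with `name`, `color`
#' (hex or 3/4 channel values) and optional `clear` flag.
#'
#' @param path Palette file (`.yaml`/`.yml`/`.json`).
#' @return A [material_palette()].
#' @export
read_material_palette <- function(path) {
  if (!file.exists(path)) stop_io("palette file does not exist: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  mats <- cfg$materials %||% cfg
  nm <- vapply(mats, function(m) m$name, "")
  cols <- lapply(mats, function(m) m$color)
  colm <- if (all(vapply(cols, is.character, TRUE))) {
    unlist(cols)
  } else {
    do.call(rbind, lapply(cols, function(cc) as.numeric(unlist(cc))))
  }
  clear <- vapply(mats, function(m) isTRUE(m$clear), TRUE)
  material_palette(nm, colm, clear)
}

#' Dither one RGBA slice into per-pixel material assignments
#'
#' Floyd-Steinberg error diffusion: each pixel with alpha > 0 is assigned the
#' palette entry nearest (Euclidean distance in linear-light RGB) to its
#' error-adjusted colour; the quantisation error is diffused to unprocessed
#' neighbours with weights 7/16, 3/16, 5/16, 1/16 in serpentine row order.
#' Alpha-0 pixels map to the no-material sentinel `0` and neither receive nor
#' absorb error. Deterministic: identical input, palette and scan order give
#' bit-identical output.
#'
#' @param img `nx x ny x 4` sRGB RGBA array, channels in `[0, 1]`.
#' @param palette A [material_palette()].
#' @return Integer `nx x ny` matrix: `0` = no material, else palette index.
#' @export
dither_slice <- function(img, palette) {
  stopifnot(inherits(palette, "material_palette"))
  if (length(dim(img)) != 3L || dim(img)[3] != 4L) {
    stop_config("img must be an nx x ny x 4 RGBA array")
  }
  if (min(img) < 0 || max(img) > 1) stop_config("image channels must lie in [0, 1]")
  lin <- img[, , 1:3, drop = FALSE]
  lin[] <- srgb_to_linear(lin)
  alive <- matrix(img[, , 4] > 0, dim(img)[1], dim(img)[2])
  pal_lin <- srgb_to_linear(palette$rgba[, 1:3, drop = FALSE])
  .fs_dither(lin, alive, pal_lin)
}

#' Dither every layer of a colour slice stack
#'
#' @param stack A `color_slice_stack` from [colorize_stack()].
#' @param palette A [material_palette()].
#' @return A `material_slice_stack`: integer rasters plus inherited geometry.
#' @export
dither_stack <- function(stack, palette = default_material_palette()) {
  stopifnot(inherits(stack, "color_slice_stack"))
  slices <- lapply(stack$slices, dither_slice, palette = palette)
  structure(list(slices = slices, palette = palette,
                 pitch = stack$pitch, layer_mm = stack$layer_mm,
                 z_mm = stack$z_mm, origin_xy = stack$origin_xy),
            class = "material_slice_stack")
}

#' @export
print.material_slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<material_slice_stack> %d layers of %d x %d px over %d materials\n",
              length(x$slices), d[1], d[2], length(x$palette$names)))
  invisible(x)
}

#' Material usage fractions over a region
#'
#' Audits the dithered output: the fraction of each material among
#' non-sentinel pixels in the region. Error diffusion preserves mean colour,
#' so for a uniform target inside the palette's hull these fractions recover
#' the mixing ratios.
#'
#' @param stack A `material_slice_stack`.
#' @param region Optional logical array congruent with the stack's rasters
#'   (`nx x ny x nlayer`); default the whole stack.
#' @return Tibble with columns `material`, `count`, `fraction` (sums to 1).
#' @export
material_fractions <- function(stack, region = NULL) {
  stopifnot(inherits(stack, "material_slice_stack"))
  d <- c(dim(stack$slices[[1]]), length(stack$slices))
  idx <- array(unlist(stack$slices), d)
  if (!is.null(region)) {
    if (!identical(dim(region), d)) {
      stop_data("region shape [", paste(dim(region), collapse = ", "),
                "] does not match stack rasters [", paste(d, collapse = ", "), "]")
    }
    idx <- idx[region]
  }
  idx <- idx[idx > 0L]
  if (length(idx) == 0L) {
    stop(errorCondition("region contains no material pixels",
                        class = c("vxp_empty_region", "vxp_data_error", "vxp_error")))
  }
  k <- length(stack$palette$names)
  counts <- tabulate(idx, nbins = k)
  tibble::tibble(material = stack$palette$names, count = counts,
                 fraction = counts / sum(counts))
}

#' Write a material slice stack to disk
#'
#' Two layouts: `indexed_png` writes one 8-bit index raster per layer (pixel
#' value = material index, 0 = no material, stored as value/255 gray);
#' `per_material_bitmaps` writes K binary PNGs per layer, one per material
#' channel with pixels set where that material is deposited — the
#' droplet-deposition form. A `manifest.json` records mode, palette and
#' geometry so [read_material_stack()] can reconstruct the stack from either
#' layout.
#'
#' @param stack A `material_slice_stack`.
#' @param dir Output directory.
#' @param mode `"indexed_png"` or `"per_material_bitmaps"`.
#' @return Tibble manifest (file, bytes) with attribute `total_bytes`.
#' @export
write_material_stack <- function(stack, dir,
                                 mode = c("indexed_png", "per_material_bitmaps")) {
  mode <- match.arg(mode)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop_io("cannot create directory ", dir)
  }
  k <- length(stack$palette$names)
  files <- character(0)
  for (i in seq_along(stack$slices)) {
    s <- stack$slices[[i]]
    if (mode == "indexed_png") {
      f <- file.path(dir, sprintf("slice_%04d.png", i - 1L))
      ok <- tryCatch({png::writePNG(t(s) / 255, f); TRUE}, error = function(e) FALSE)
      if (!ok) stop_io("failed to write ", f)
      files <- c(files, f)
    } else {
      for (mat in seq_len(k)) {
        f <- file.path(dir, sprintf("slice_%04d_m%d.png", i - 1L, mat))
        ok <- tryCatch({png::writePNG(t(s == mat) * 1, f); TRUE},
                       error = function(e) FALSE)
        if (!ok) stop_io("failed to write ", f)
        files <- c(files, f)
      }
    }
  }
  bytes <- file.size(files)
  man <- tibble::tibble(file = basename(files), bytes = bytes)
  meta <- list(kind = "material_slice_stack", mode = mode,
               layers = length(stack$slices), materials = stack$palette$names,
               colors = apply(stack$palette$rgba, 1, function(r)
                 grDevices::rgb(r[1], r[2], r[3], r[4])),
               clear = stack$palette$clear,
               pitch_x_mm = stack$pitch[1], pitch_y_mm = stack$pitch[2],
               layer_mm = stack$layer_mm, z0_mm = stack$z_mm[1],
               origin_xy_mm = stack$origin_xy,
               total_bytes = sum(bytes), files = man$file)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(man, "total_bytes") <- sum(bytes)
  man
}

#' Read back a material slice stack written by [write_material_stack()]
#'
#' @param dir Directory containing the rasters and `manifest.json`.
#' @return A `material_slice_stack`.
#' @export
read_material_stack <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_io("no manifest.json in ", dir)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  palette <- material_palette(meta$materials, meta$colors, meta$clear)
  k <- length(meta$materials)
  slices <- vector("list", meta$layers)
  for (i in seq_len(meta$layers)) {
    if (meta$mode == "indexed_png") {
      f <- file.path(dir, sprintf("slice_%04d.png", i - 1L))
      slices[[i]] <- t(round(png::readPNG(f) * 255))
      storage.mode(slices[[i]]) <- "integer"
    } else {
      acc <- NULL
      for (mat in seq_len(k)) {
        f <- file.path(dir, sprintf("slice_%04d_m%d.png", i - 1L, mat))
        bit <- t(png::readPNG(f)) > 0.5
        if (is.null(acc)) acc <- matrix(0L, nrow(bit), ncol(bit))
        acc[bit] <- mat
      }
      slices[[i]] <- acc
    }
  }
  structure(list(slices = slices, palette = palette,
                 pitch = c(meta$pitch_x_mm, meta$pitch_y_mm),
                 layer_mm = meta$layer_mm,
                 z_mm = meta$z0_mm + (seq_len(meta$layers) - 1) * meta$layer_mm,
                 origin_xy = as.numeric(meta$origin_xy_mm)),
            class = "material_slice_stack")
}
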