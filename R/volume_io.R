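#' Volumetric scalar image with physical geometry
#'
#' An `image_volume` is the package's container for a 3D scalar field sampled
#' on a regular anisotropic grid: a numeric array of intensities in scanner
#' units (Hounsfield for CT, arbitrary signal for MR) plus the physical voxel
#' spacing and the position of the first voxel centre. The axis convention is
#' fixed: the first array index runs along the in-plane x axis, the second
#' along in-plane y, and the third along the slice (z) axis, with slice index
#' increasing with physical z.
#'
#' @param voxels Numeric 3D array of intensities. All values must be finite.
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm, all positive.
#' @param origin Numeric length-3 vector, physical position (mm) of the centre
#'   of voxel `[1, 1, 1]`. Defaults to the zero vector.
#'
#' @return An object of class `image_volume` with fields `voxels`, `spacing`,
#'   `origin` and `axes` (the convention tag, `"xyz"`).
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 3)), spacing = c(0.8, 0.8, 3))
#' dim(vol$voxels)
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_data("voxels must be a 3D array, got dimensions [",
              paste(dim(voxels), collapse = ", "), "]")
  }
  if (any(dim(voxels) < 1L)) stop_data("all three dimensions must be positive")
  if (!all(is.finite(voxels))) stop_data("voxel intensities must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_data("spacing must be three positive values (mm)")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop_data("origin must be three finite values (mm)")
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, axes = "xyz"),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.6g, %.6g], origin (%.4g, %.4g, %.4g) mm\n",
              min(x$voxels), max(x$voxels),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Binary anatomy mask congruent with an image volume
#'
#' @param voxels Logical (or 0/1 numeric) 3D array; `TRUE` marks the anatomy
#'   of interest.
#' @param vol Optional `image_volume` to check congruence against.
#' @return Logical 3D array of class `vxp_mask`.
#' @export
as_mask <- function(voxels, vol = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_data("mask must be a 3D array")
  }
  m <- array(as.logical(voxels), dim(voxels))
  if (anyNA(m)) stop_data("mask contains NA values")
  if (!is.null(vol) && !identical(dim(m), dim(vol$voxels))) {
    stop_data("mask shape [", paste(dim(m), collapse = ", "),
              "] does not match volume shape [",
              paste(dim(vol$voxels), collapse = ", "), "]")
  }
  class(m) <- c("vxp_mask", class(m))
  m
}

#' Display window (window/level) in scanner units
#'
#' @param center Window centre (level), scanner units.
#' @param width Window width, must be > 0.
#' @return A `window_level` object.
#' @export
window_level <- function(center, width) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0) {
    stop_config("window width must be a single positive number, got ", width)
  }
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center)) {
    stop_config("window center must be a single finite number")
  }
  structure(list(center = as.numeric(center), width = as.numeric(width)),
            class = "window_level")
}

#' Read a volume from a DICOM series directory or a NIfTI file
#'
#' For a DICOM series the directory must contain at least two single-frame
#' slices of one series; slices are ordered by ascending physical position
#' along the slice axis and the inter-slice distance (relative spread up to
#' `1e-3` tolerated, mean used) becomes `dz`. For NIfTI, voxel dimensions come
#' from the header.
#'
#' @param path Directory (DICOM series) or file (`.nii`/`.nii.gz`).
#' @param format `"auto"`, `"dicom_series"` or `"single_file"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "dicom_series", "single_file")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("path does not exist: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series" else "single_file"
  }
  if (format == "dicom_series") {
    read_dicom_series(path)
  } else {
    read_nifti_volume(path)
  }
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_io("failed to read NIfTI file ",
                                              path, ": ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L) {
    stop_data("expected a 3D NIfTI volume, got dimensions [",
              paste(dim(arr), collapse = ", "), "]")
  }
  pd <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(arr), dim(arr)), spacing = pd)
}

#' Write a volume to a NIfTI file
#'
#' @param vol An [image_volume()].
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stop_io("failed to write ", path, ": ",
                                       conditionMessage(e)))
  invisible(path)
}

#' Read a mask from a NIfTI file or a PNG stack directory (nonzero = TRUE)
#'
#' @param path NIfTI file or a directory of per-slice PNGs in z order.
#' @param vol Optional volume to check congruence against.
#' @return A logical mask array (see [as_mask()]).
#' @export
read_mask <- function(path, vol = NULL) {
  if (!file.exists(path)) stop_io("mask path does not exist: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop_io("no PNG files in mask directory ", path)
    slices <- lapply(files, function(f) {
      px <- png::readPNG(f)
      if (length(dim(px)) == 3L) px <- px[, , 1]
      # PNG rows are y, columns are x; store as [x, y]
      t(px)
    })
    d <- dim(slices[[1]])
    if (!all(vapply(slices, function(s) identical(dim(s), d), logical(1)))) {
      stop_data("mask PNG slices have inconsistent dimensions")
    }
    arr <- array(unlist(slices), c(d, length(slices)))
    as_mask(arr > 0, vol)
  } else {
    img <- as.array(RNifti::readNifti(path))
    as_mask(img > 0, vol)
  }
}

#' Apply a window/level mapping to the working display range `[0, 1]`
#'
#' Intensities are rescaled linearly so that
#' `[center - width/2, center + width/2]` maps onto `[0, 1]`, clamping
#' outside; geometry is unchanged. Downstream stages (partitioning, LUT,
#' slicing) operate in this normalised working domain.
#'
#' @param vol An [image_volume()].
#' @param wl A [window_level()].
#' @return A windowed [image_volume()] with intensities in `[0, 1]`.
#' @examples
#' v <- image_volume(array(c(0, 50, 100, 200), c(4, 1, 1)), c(1, 1, 1))
#' apply_window_level(v, window_level(50, 100))$voxels[, 1, 1]
#' @export
apply_window_level <- function(vol, wl) {
  if (!inherits(wl, "window_level")) wl <- window_level(wl[[1]], wl[[2]])
  lo <- wl$center - wl$width / 2
  x <- (vol$voxels - lo) / wl$width
  x[x < 0] <- 0
  x[x > 1] <- 1
  image_volume(x, vol$spacing, vol$origin)
}

#' Intensity bounds over the masked region
#'
#' The masked bounds seed the equal-width partition: the total range of the
#' isolated anatomy is what gets divided into N intervals.
#'
#' @param vol An [image_volume()].
#' @param mask Logical mask congruent with `vol`; must select at least one voxel.
#' @return Named numeric vector `c(lo = min, hi = max)` over masked voxels.
#' @export
compute_bounds <- function(vol, mask) {
  mask <- as_mask(mask, vol)
  if (!any(mask)) stop_data("mask selects no voxels; bounds are undefined")
  v <- vol$voxels[mask]
  c(lo = min(v), hi = max(v))
}

#' Crop a volume (and mask) to the mask's axis-aligned bounding box
#'
#' Stand-in for interactive cropping: keeps only the box of slices/rows/columns
#' that contain masked anatomy, with an optional margin in voxels.
#'
#' @param vol An [image_volume()].
#' @param mask Logical mask congruent with `vol`.
#' @param margin Non-negative integer margin (voxels) retained around the box.
#' @return List with cropped `vol` and `mask`.
#' @export
crop_to_mask <- function(vol, mask, margin = 0L) {
  mask <- as_mask(mask, vol)
  if (!any(mask)) stop_data("cannot crop to an empty mask")
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  vv <- vol$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mm <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- vol$origin + (lo - 1L) * vol$spacing
  list(vol = image_volume(vv, vol$spacing, origin), mask = as_mask(mm))
}

# Physical volume (mm^3) of the masked region: voxel count x voxel volume.
masked_volume_mm3 <- function(vol, mask) {
  sum(mask) * prod(vol$spacing)
}
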