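# Minimal single-frame DICOM series I/O, Explicit VR Little Endian only.
# Scope: grayscale CT/MR-style slices with 16-bit unsigned pixels and linear
# rescale (slope/intercept) — everything read_volume() needs to round-trip the
# geometry and intensities written by write_phantom_dicom(). Not a general
# DICOM implementation.

UID_ROOT <- "1.2.826.0.1.3680043.10.1457"  # generic org-root style prefix
TS_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"

u16le <- function(x) {
  x <- as.integer(round(x))
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

# even-length padded string bytes; UIs pad with NUL, text VRs with space
str_bytes <- function(s, pad = charToRaw(" ")) {
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L) b <- c(b, pad)
  b
}

# One Explicit-VR data element. Short-form VRs carry a 16-bit length;
# OB/OW/UT/UN/SQ carry 2 reserved bytes + 32-bit length.
dcm_element <- function(group, elem, vr, bytes) {
  long_form <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  len <- length(bytes)
  header <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (long_form) {
    c(header, as.raw(c(0, 0)), u32le(len), bytes)
  } else {
    if (len > 65535L) stop_io("element length overflow for short-form VR ", vr)
    c(header, u16le(len), bytes)
  }
}

dcm_str <- function(group, elem, vr, s) {
  pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  dcm_element(group, elem, vr, str_bytes(s, pad = pad))
}

dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", u16le(x))

# Decimal String formatting: DICOM DS is limited to 16 bytes per value.
ds_fmt <- function(x) {
  paste(vapply(x, function(v) formatC(v, format = "g", digits = 10), ""),
        collapse = "\\")
}

new_uid <- function(suffix) paste(UID_ROOT, suffix, sep = ".")

#' @noRd
write_dicom_slice <- function(path, pixels_u16, nx, ny, spacing, position,
                              instance, series_uid, study_uid,
                              slope, intercept) {
  body <- c(
    dcm_str(0x0008, 0x0016, "UI", SOP_SECONDARY_CAPTURE),
    dcm_str(0x0008, 0x0018, "UI", new_uid(paste0("3.", instance))),
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_str(0x0018, 0x0050, "DS", ds_fmt(spacing[3])),
    dcm_str(0x0018, 0x0088, "DS", ds_fmt(spacing[3])),
    dcm_str(0x0020, 0x000D, "UI", study_uid),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0011, "IS", "1"),
    dcm_str(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_str(0x0020, 0x0032, "DS", ds_fmt(position)),
    dcm_str(0x0020, 0x0037, "DS", ds_fmt(c(1, 0, 0, 0, 1, 0))),
    dcm_us(0x0028, 0x0002, 1),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, ny),             # Rows
    dcm_us(0x0028, 0x0011, nx),             # Columns
    dcm_str(0x0028, 0x0030, "DS", ds_fmt(c(spacing[2], spacing[1]))),  # row\col
    dcm_us(0x0028, 0x0100, 16),
    dcm_us(0x0028, 0x0101, 16),
    dcm_us(0x0028, 0x0102, 15),
    dcm_us(0x0028, 0x0103, 0),
    dcm_str(0x0028, 0x1052, "DS", ds_fmt(intercept)),
    dcm_str(0x0028, 0x1053, "DS", ds_fmt(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", u16le(pixels_u16))
  )
  meta <- c(
    dcm_str(0x0002, 0x0002, "UI", SOP_SECONDARY_CAPTURE),
    dcm_str(0x0002, 0x0003, "UI", new_uid(paste0("3.", instance))),
    dcm_str(0x0002, 0x0010, "UI", TS_EXPLICIT_VR_LE)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", u32le(length(meta))), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 128L)), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# -- reading ------------------------------------------------------------------

read_u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}

read_u32 <- function(raw, at) {
  sum(as.numeric(raw[at + 0:3]) * c(1, 256, 65536, 16777216))
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse all top-level elements of one Explicit-VR-LE file into a named list
# keyed "gggg,eeee" -> raw payload.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM") {
    stop_io("not a DICOM file (missing DICM magic): ", path)
  }
  pos <- 133L
  out <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- read_u16(raw, pos); elem <- read_u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(raw, pos + 8L)
      data_at <- pos + 12L
    } else {
      len <- read_u16(raw, pos + 6L)
      data_at <- pos + 8L
    }
    if (data_at + len - 1L > n) {
      stop_io("truncated DICOM element at byte ", pos, " in ", path)
    }
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- if (len > 0) raw[data_at:(data_at + len - 1L)] else raw(0)
    pos <- data_at + len
  }
  out
}

tag_str <- function(elems, key, path) {
  b <- elems[[key]]
  if (is.null(b)) stop_io("DICOM file ", path, " is missing tag (", key, ")")
  trimws(rawToChar(b[b != as.raw(0L)]))
}

tag_ds <- function(elems, key, path) {
  as.numeric(strsplit(tag_str(elems, key, path), "\\\\")[[1]])
}

tag_us <- function(elems, key, path) {
  b <- elems[[key]]
  if (is.null(b)) stop_io("DICOM file ", path, " is missing tag (", key, ")")
  read_u16(b, 1L)
}

#' @noRd
read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) == 0L) {
    files <- sort(list.files(dir, full.names = TRUE))
    files <- files[!dir.exists(files)]
  }
  if (length(files) < 2L) {
    stop_data("a DICOM series needs at least 2 slices; found ",
              length(files), " in ", dir)
  }
  slices <- lapply(files, function(f) {
    elems <- tryCatch(parse_dicom_file(f),
                      error = function(e) stop_io("failed to read ", f, ": ",
                                                  conditionMessage(e)))
    nx <- tag_us(elems, "0028,0011", f)  # Columns
    ny <- tag_us(elems, "0028,0010", f)  # Rows
    ps <- tag_ds(elems, "0028,0030", f)  # row spacing \ column spacing
    ipp <- tag_ds(elems, "0020,0032", f)
    slope <- tag_ds(elems, "0028,1053", f)
    intercept <- tag_ds(elems, "0028,1052", f)
    pix <- elems[["7fe0,0010"]]
    if (is.null(pix)) stop_io("DICOM file ", f, " has no pixel data")
    vals <- readBin(pix, "integer", n = nx * ny, size = 2L,
                    signed = FALSE, endian = "little")
    if (length(vals) != nx * ny) stop_io("pixel data size mismatch in ", f)
    list(file = f, nx = nx, ny = ny, dx = ps[2], dy = ps[1], z = ipp[3],
         xy0 = ipp[1:2], vals = vals * slope + intercept)
  })
  nx <- vapply(slices, `[[`, 0L, "nx")
  ny <- vapply(slices, `[[`, 0L, "ny")
  if (length(unique(nx)) != 1L || length(unique(ny)) != 1L) {
    stop_data("inconsistent in-plane dimensions across series slices in ", dir)
  }
  ord <- order(vapply(slices, `[[`, 0, "z"))
  slices <- slices[ord]
  z <- vapply(slices, `[[`, 0, "z")
  dz <- diff(z)
  if (any(dz <= 0)) stop_data("duplicate or non-increasing slice positions in ", dir)
  spread <- (max(dz) - min(dz)) / mean(dz)
  if (spread > 1e-3) {
    stop_data(sprintf(paste0("non-uniform inter-slice spacing in %s: steps in ",
                             "[%.6g, %.6g] mm (relative spread %.3g > 1e-3); ",
                             "is a slice missing?"),
                      dir, min(dz), max(dz), spread))
  }
  arr <- array(0, c(nx[1], ny[1], length(slices)))
  for (k in seq_along(slices)) {
    # pixel data is row-major: x (column index) varies fastest
    arr[, , k] <- matrix(slices[[k]]$vals, nrow = nx[1])
  }
  image_volume(arr, spacing = c(slices[[1]]$dx, slices[[1]]$dy, mean(dz)),
               origin = c(slices[[1]]$xy0, z[1]))
}
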