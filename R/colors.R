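# sRGB <-> linear-light conversions (IEC 61966-2-1). All colour blending and
# palette distance computations happen in linear light; stored rasters are sRGB.

srgb_to_linear <- function(c) {
  ifelse(c <= 0.04045, c / 12.92, ((c + 0.055) / 1.055)^2.4)
}

linear_to_srgb <- function(c) {
  c <- pmin(pmax(c, 0), 1)
  ifelse(c <= 0.0031308, 12.92 * c, 1.055 * c^(1 / 2.4) - 0.055)
}

# hex "#RRGGBB"/"#RRGGBBAA" -> RGBA in [0,1]
hex_to_rgba <- function(hex) {
  m <- grDevices::col2rgb(hex, alpha = TRUE) / 255
  t(m)[, c("red", "green", "blue", "alpha"), drop = FALSE]
}

# Accept an n x 4 matrix, an n x 3 matrix (alpha 1) or character hex colours;
# return an n x 4 matrix with channels in [0, 1].
as_rgba_matrix <- function(colors) {
  if (is.character(colors)) {
    out <- hex_to_rgba(colors)
  } else {
    out <- as.matrix(colors)
    if (ncol(out) == 3L) out <- cbind(out, 1)
    if (ncol(out) != 4L) stop_config("colors must be hex strings or an n x 3/4 matrix")
  }
  if (any(out < 0) || any(out > 1) || anyNA(out)) {
    stop_config("color channels must lie in [0, 1]")
  }
  dimnames(out) <- list(NULL, c("r", "g", "b", "a"))
  out
}
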