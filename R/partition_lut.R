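#' Equal-width partition of an intensity range
#'
#' Divides `[lo, hi]` into `n` contiguous, equal-width divisions with no gap
#' and no overlap: `n + 1` equally spaced edges spanning the range exactly.
#' Divisions are half-open `[e_i, e_{i+1})` except the last, which is closed
#' so the maximum belongs to division `n`.
#'
#' @param lo,hi Range bounds (working intensity units); `hi > lo`.
#' @param n Number of divisions, integer >= 1. The printed-model studies use
#'   2, 4 and 10.
#' @return A `partition` object with fields `n_divisions` and `edges`.
#' @examples
#' partition_range(0, 100, 4)$edges
#' @export
partition_range <- function(lo, hi, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop_config("n must be a single integer >= 1, got ", n)
  }
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop_data("need hi > lo, got [", lo, ", ", hi, "]")
  }
  n <- as.integer(n)
  edges <- seq(lo, hi, length.out = n + 1L)
  edges[1] <- lo
  edges[n + 1L] <- hi
  structure(list(n_divisions = n, edges = edges), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d equal divisions over [%.6g, %.6g]\n",
              x$n_divisions, x$edges[1], x$edges[x$n_divisions + 1L]))
  invisible(x)
}

#' Map intensities to division indices
#'
#' Vectorised. Division `i` is `[e_i, e_{i+1})`; the upper bound `hi` maps to
#' division `n`. Out-of-range intensities return the sentinel `NA`.
#'
#' @param intensity Numeric vector (or array) of intensities.
#' @param p A [partition_range()] object.
#' @return Integer vector/array of division indices in `1..n`, `NA` outside
#'   the range.
#' @export
assign_division <- function(intensity, p) {
  stopifnot(inherits(p, "partition"))
  idx <- findInterval(intensity, p$edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > p$n_divisions] <- NA_integer_
  idx[is.na(intensity)] <- NA_integer_
  if (!is.null(dim(intensity))) dim(idx) <- dim(intensity)
  idx
}

#' Default division target colours
#'
#' Palettes follow the printed-model studies: 2 divisions use cyan and
#' magenta; 4 add yellow and black; 10 use cyan, magenta, yellow, black,
#' white plus red, orange, green, blue and violet — the latter five are
#' non-material target colours reproduced at print time as dithered mixtures
#' of the base resins. Exact resin colour coordinates are proprietary, so
#' nominal sRGB values are used; override via the `colors` argument of
#' [color_lut()]. Other `n` fall back to a perceptually ordered ramp.
#'
#' @param n Number of divisions.
#' @return `n` x 4 RGBA matrix, channels in `[0, 1]`.
#' @export
default_division_colors <- function(n) {
  named <- switch(as.character(n),
    "1" = "#808080",
    "2" = c("#00FFFF", "#FF00FF"),
    "4" = c("#00FFFF", "#FF00FF", "#FFFF00", "#000000"),
    "10" = c("#00FFFF", "#FF00FF", "#FFFF00", "#000000", "#FFFFFF",
             "#FF0000", "#FF8000", "#00FF00", "#0000FF", "#8000FF"),
    grDevices::hcl.colors(n, "viridis")
  )
  as_rgba_matrix(named)
}

#' Colour lookup table over a partition
#'
#' Maps working intensities to RGBA target colours: each division carries one
#' colour; with `blend_mode = "linear"` a band of width
#' `blend_fraction * division width` on each side of an interior edge is
#' linearly interpolated (in linear-light RGB) between the two adjacent
#' division colours, producing the smooth gradients between regions of
#' distinct colour. `blend_fraction = 0` reproduces hard boundaries exactly.
#'
#' @param partition A [partition_range()] object.
#' @param colors One colour per division: hex strings or an `n` x 3/4 matrix.
#'   Default [default_division_colors()].
#' @param blend_mode `"hard"` or `"linear"`.
#' @param blend_fraction Fraction of a division's width blended at each
#'   boundary, in `[0, 0.5]`. Default 0.25.
#' @return A `color_lut` object.
#' @export
color_lut <- function(partition, colors = NULL,
                      blend_mode = c("hard", "linear"), blend_fraction = 0.25) {
  stopifnot(inherits(partition, "partition"))
  blend_mode <- match.arg(blend_mode)
  n <- partition$n_divisions
  colors <- if (is.null(colors)) default_division_colors(n) else as_rgba_matrix(colors)
  if (nrow(colors) != n) {
    stop_config("need exactly ", n, " division colors, got ", nrow(colors))
  }
  if (!is.numeric(blend_fraction) || length(blend_fraction) != 1L ||
      is.na(blend_fraction) || blend_fraction < 0 || blend_fraction > 0.5) {
    stop_config("blend_fraction must lie in [0, 0.5]")
  }
  structure(list(partition = partition, division_colors = colors,
                 blend_mode = blend_mode, blend_fraction = blend_fraction),
            class = "color_lut")
}

#' @export
print.color_lut <- function(x, ...) {
  cat(sprintf("<color_lut> %d divisions, %s boundaries%s\n",
              x$partition$n_divisions, x$blend_mode,
              if (x$blend_mode == "linear")
                sprintf(" (blend fraction %.3g)", x$blend_fraction) else ""))
  invisible(x)
}

#' Evaluate a colour LUT at given intensities
#'
#' Vectorised. In-range intensities get their division's colour (blended near
#' interior edges in linear mode); out-of-range intensities get the fully
#' transparent colour, signalling "no material".
#'
#' @param intensity Numeric vector of working intensities.
#' @param lut A [color_lut()].
#' @return `length(intensity)` x 4 sRGB RGBA matrix, channels in `[0, 1]`.
#' @export
lut_color <- function(intensity, lut) {
  stopifnot(inherits(lut, "color_lut"))
  p <- lut$partition
  n <- p$n_divisions
  div <- assign_division(intensity, p)
  out <- matrix(0, length(intensity), 4,
                dimnames = list(NULL, c("r", "g", "b", "a")))
  ok <- !is.na(div)
  if (!any(ok)) return(out)
  d <- div[ok]
  cols_lin <- cbind(srgb_to_linear(lut$division_colors[, 1:3, drop = FALSE]),
                    lut$division_colors[, 4])
  if (lut$blend_mode == "hard" || lut$blend_fraction == 0) {
    res <- cols_lin[d, , drop = FALSE]
  } else {
    bf <- lut$blend_fraction
    e_lo <- p$edges[d]
    w <- p$edges[d + 1L] - e_lo
    t_rel <- (intensity[ok] - e_lo) / w
    res <- cols_lin[d, , drop = FALSE]
    # lower blend band: interpolate toward the previous division's colour
    low <- t_rel < bf & d > 1L
    if (any(low)) {
      s <- 0.5 + 0.5 * t_rel[low] / bf   # weight of own colour: 0.5 at the edge
      res[low, ] <- s * cols_lin[d[low], , drop = FALSE] +
        (1 - s) * cols_lin[d[low] - 1L, , drop = FALSE]
    }
    # upper blend band: interpolate toward the next division's colour
    high <- t_rel > 1 - bf & d < n
    if (any(high)) {
      s <- 0.5 + 0.5 * (1 - t_rel[high]) / bf
      res[high, ] <- s * cols_lin[d[high], , drop = FALSE] +
        (1 - s) * cols_lin[d[high] + 1L, , drop = FALSE]
    }
  }
  out[ok, 1:3] <- linear_to_srgb(res[, 1:3, drop = FALSE])
  out[ok, 4] <- res[, 4]
  out
}

#' Serialise a LUT as a plain-text transfer-function table
#'
#' Writes one `intensity R G B A` row per breakpoint (edges, division
#' midpoints and blend-band boundaries), the piecewise-linear form common
#' volume-rendering transfer-function importers accept.
#'
#' @param lut A [color_lut()].
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_lut <- function(lut, path) {
  p <- lut$partition
  n <- p$n_divisions
  e <- p$edges
  w <- diff(e)
  pts <- c(e, e[-(n + 1L)] + w / 2)
  if (lut$blend_mode == "linear" && lut$blend_fraction > 0) {
    pts <- c(pts, e[-(n + 1L)] + lut$blend_fraction * w,
             e[-1L] - lut$blend_fraction * w)
  }
  pts <- sort(unique(pts))
  cols <- lut_color(pts, lut)
  tab <- cbind(intensity = pts, cols)
  utils::write.table(format(tab, digits = 9, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
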