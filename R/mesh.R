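#' Threshold label map over a partition
#'
#' The conventional workflow's segmentation step: every in-mask voxel whose
#' intensity falls in division `i`'s range gets label `i`; everything else is
#' the sentinel `NA`. Divisions are sequential with no overlap and no gap, so
#' each in-mask, in-range voxel carries exactly one label.
#'
#' @param vol An [image_volume()].
#' @param mask Logical mask congruent with `vol`.
#' @param p A [partition_range()] object derived from this volume's masked
#'   bounds.
#' @return A `label_map`: integer array (NA sentinel) plus geometry.
#' @export
build_label_map <- function(vol, mask, p) {
  stopifnot(inherits(p, "partition"))
  mask <- as_mask(mask, vol)
  b <- compute_bounds(vol, mask)
  n <- p$n_divisions
  tol <- 1e-9 * max(1, abs(b))
  if (b["lo"] < p$edges[1] - tol || b["hi"] > p$edges[n + 1L] + tol) {
    stop_data(sprintf("partition bounds [%g, %g] do not cover the masked intensity range [%g, %g]",
                      p$edges[1], p$edges[n + 1L], b["lo"], b["hi"]))
  }
  labels <- array(NA_integer_, dim(vol$voxels))
  labels[mask] <- assign_division(vol$voxels[mask], p)
  structure(list(labels = labels, n_divisions = n,
                 spacing = vol$spacing, origin = vol$origin),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d divisions over %s voxels (%d labelled)\n",
              x$n_divisions, paste(dim(x$labels), collapse = " x "),
              sum(!is.na(x$labels))))
  invisible(x)
}

new_mesh <- function(vertices, faces, division = NA_integer_) {
  structure(list(vertices = vertices, faces = faces, division = division),
            class = "vxp_mesh")
}

#' @export
print.vxp_mesh <- function(x, ...) {
  cat(sprintf("<mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.na(x$division)) sprintf(" (division %d)", x$division) else ""))
  invisible(x)
}

#' Extract the boundary surface of one division
#'
#' Isosurface at level 0.5 of the division's binary indicator volume, scaled
#' to physical mm. Each division is meshed independently, with no face
#' sharing between divisions — deliberately reproducing the mechanism by
#' which gaps form between adjacent threshold segments in the boundary-
#' surface workflow. The surface is closed (watertight) and consistently
#' oriented by construction.
#'
#' @param labelmap A [build_label_map()] result.
#' @param division Division index in `1..n_divisions`.
#' @return A `vxp_mesh` (0 faces if the division has no voxels, with a
#'   warning).
#' @export
extract_mesh <- function(labelmap, division) {
  stopifnot(inherits(labelmap, "label_map"))
  if (division < 1L || division > labelmap$n_divisions) {
    stop_config("division must be in 1..", labelmap$n_divisions)
  }
  ind <- !is.na(labelmap$labels) & labelmap$labels == division
  if (!any(ind)) {
    warning("division ", division, " contains no voxels; returning empty mesh")
    return(new_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), division))
  }
  res <- .marching_tets(as.logical(ind), dim(ind),
                        labelmap$spacing, labelmap$origin)
  new_mesh(res$vertices, res$faces, as.integer(division))
}

# Undirected edge keys of all faces: 3L-per-face integer vector encoding
# (min, max) vertex pairs.
face_edge_keys <- function(m) {
  f <- m$faces
  nv <- nrow(m$vertices)
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  (as.numeric(lo) - 1) * nv + hi
}

#' Is a mesh watertight?
#'
#' Closed surfaces have every undirected edge shared by exactly two faces.
#'
#' @param m A `vxp_mesh`.
#' @return `TRUE`/`FALSE`, with attribute `boundary_edges` (count of edges
#'   not shared by exactly two faces).
#' @export
is_watertight <- function(m) {
  if (nrow(m$faces) == 0L) return(structure(FALSE, boundary_edges = 0L))
  tab <- table(face_edge_keys(m))
  bad <- sum(tab != 2L)
  structure(bad == 0L, boundary_edges = as.integer(bad))
}

# Merge coincident vertices (needed after reading triangle-soup STL files).
weld_mesh <- function(m, digits = 6) {
  if (nrow(m$vertices) == 0L) return(m)
  key <- apply(round(m$vertices, digits), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- m$vertices[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid[m$faces], ncol = 3)
  new_mesh(verts, faces, m$division)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume via the divergence theorem — the sum of signed tetrahedron
#' volumes from the origin to each face — with the absolute value returned,
#' so the result is translation- and orientation-sign-invariant. The mesh
#' must be watertight; open meshes raise a data error reporting the number
#' of boundary edges.
#'
#' @param m A `vxp_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(m) {
  if (nrow(m$faces) == 0L) return(0)
  wt <- is_watertight(m)
  if (!wt) {
    stop_data("mesh is not watertight: ", attr(wt, "boundary_edges"),
              " boundary edge(s); volume is undefined")
  }
  v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
  v2 <- m$vertices[m$faces[, 2], , drop = FALSE]
  v3 <- m$vertices[m$faces[, 3], , drop = FALSE]
  cx <- v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]
  cy <- v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]
  cz <- v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]
  abs(sum(v1[, 1] * cx + v1[, 2] * cy + v1[, 3] * cz)) / 6
}

#' Count disconnected mesh shells
#'
#' Connected components of the face graph under shared-edge adjacency (two
#' faces are connected iff they share an edge; touching at a single vertex
#' does not connect). Invariant under face reordering and vertex renumbering.
#'
#' @param m A `vxp_mesh`.
#' @return Integer component count (0 for an empty mesh).
#' @export
count_components <- function(m) {
  nf <- nrow(m$faces)
  if (nf == 0L) return(0L)
  keys <- face_edge_keys(m)
  face_of <- rep(seq_len(nf), 3)
  ord <- order(keys)
  keys <- keys[ord]
  face_of <- face_of[ord]
  same <- which(keys[-1] == keys[-length(keys)])
  g <- igraph::graph_from_data_frame(
    data.frame(from = face_of[same], to = face_of[same + 1L]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nf))
  )
  igraph::components(g)$no
}

#' Write meshes to a binary STL file
#'
#' Binary (not ASCII) STL: 80-byte header, triangle count, then 50 bytes per
#' facet. Multiple meshes are concatenated as separate shells in one file.
#'
#' @param mesh A `vxp_mesh` or list of them.
#' @param path Output `.stl` path.
#' @return `path`, invisibly; attribute `bytes` carries the file size.
#' @export
write_stl <- function(mesh, path) {
  meshes <- if (inherits(mesh, "vxp_mesh")) list(mesh) else mesh
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_io("cannot open ", path, " for writing"))
  open_con <- TRUE
  on.exit(if (open_con) close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  ntri <- sum(vapply(meshes, function(m) nrow(m$faces), 0L))
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  for (m in meshes) {
    if (nrow(m$faces) == 0L) next
    v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
    v2 <- m$vertices[m$faces[, 2], , drop = FALSE]
    v3 <- m$vertices[m$faces[, 3], , drop = FALSE]
    e1 <- v2 - v1
    e2 <- v3 - v1
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(nrm^2))
    len[len == 0] <- 1
    nrm <- nrm / len
    # interleave: normal, v1, v2, v3 per facet as 12 float32s
    dat <- t(cbind(nrm, v1, v2, v3))
    block <- writeBin(as.numeric(dat), raw(), size = 4L, endian = "little")
    block <- matrix(block, nrow = 48L)
    out <- rbind(block, matrix(as.raw(0L), nrow = 2L, ncol = ncol(block)))
    writeBin(as.vector(out), con)
  }
  close(con)
  open_con <- FALSE
  invisible(structure(path, bytes = file.size(path)))
}

#' Read a binary STL file
#'
#' Returns the triangle soup welded back into an indexed mesh (coincident
#' vertices merged), suitable for [mesh_volume()] and [count_components()].
#'
#' @param path Input `.stl` path.
#' @return A `vxp_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop_io("STL file does not exist: ", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 84L) stop_io("not a binary STL file: ", path)
  ntri <- readBin(raw[81:84], "integer", 1L, size = 4L, endian = "little")
  need <- 84L + 50 * ntri
  if (length(raw) < need) stop_io("truncated STL file: ", path)
  body <- raw[85:need]
  body <- matrix(body, nrow = 50L)
  floats <- readBin(as.vector(body[1:48, , drop = FALSE]), "numeric",
                    n = 12L * ntri, size = 4L, endian = "little")
  fm <- matrix(floats, nrow = 12L)
  verts <- rbind(t(fm[4:6, , drop = FALSE]),
                 t(fm[7:9, , drop = FALSE]),
                 t(fm[10:12, , drop = FALSE]))
  ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
  verts <- verts[ord, , drop = FALSE]
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  weld_mesh(new_mesh(verts, faces))
}

#' Summary metrics for one mesh
#'
#' @param m A `vxp_mesh`.
#' @param file_bytes Optional byte size of the exported STL.
#' @return One-row tibble: `n_faces`, `n_vertices`, `enclosed_volume`,
#'   `n_components`, `file_bytes`.
#' @export
mesh_metrics <- function(m, file_bytes = NA_real_) {
  tibble::tibble(
    n_faces = nrow(m$faces),
    n_vertices = nrow(m$vertices),
    enclosed_volume = if (nrow(m$faces) > 0) mesh_volume(m) else 0,
    n_components = count_components(m),
    file_bytes = as.numeric(file_bytes)
  )
}
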