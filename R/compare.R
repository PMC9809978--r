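#' Voxel-vs-mesh comparison audit
#'
#' Runs both workflows on one masked volume for each division count N and
#' measures what the boundary-surface route costs: per-division mesh faces,
#' vertices, enclosed volume, disconnected shells and STL bytes, against the
#' voxel pipeline's conserved volume and PNG-stack size (on-disk bytes and
#' the division-invariant raster payload). Volume loss is
#' reported relative to the masked source volume (voxel count x voxel
#' volume):
#' `volume_loss_percent = 100 * (1 - sum(mesh volumes) / source volume)`.
#'
#' @param vol An [image_volume()] in the working intensity domain (apply
#'   [apply_window_level()] first if needed).
#' @param mask Logical mask congruent with `vol`.
#' @param division_counts Integer vector of N values; default `c(2, 4, 10)`.
#' @param profile A [printer_profile()] for the voxel pipeline.
#' @param out_dir Directory receiving STL files, PNG stacks, CSV report and
#'   plots; default a temporary directory.
#' @param blend_mode,blend_fraction LUT settings for the voxel colour stack.
#' @return A `comparison_report` with tibbles `divisions` (per-division mesh
#'   metrics) and `summary` (per-N totals and voxel-pipeline columns).
#' @seealso [tidy.comparison_report()], [glance.comparison_report()],
#'   [autoplot.comparison_report()]
#' @export
run_comparison <- function(vol, mask, division_counts = c(2, 4, 10),
                           profile = printer_profile(), out_dir = NULL,
                           blend_mode = "linear", blend_fraction = 0.25) {
  if (length(division_counts) == 0L) {
    stop_config("division_counts must contain at least one value")
  }
  if (any(division_counts < 1)) stop_config("division counts must be >= 1")
  mask <- as_mask(mask, vol)
  out_dir <- out_dir %||% file.path(tempdir(), "voxelprint_compare")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop_io("cannot create directory ", out_dir)
  }
  b <- compute_bounds(vol, mask)
  if (b["hi"] <= b["lo"]) {
    # constant-intensity region: widen to a token range so every voxel
    # lands in division 1
    b["hi"] <- b["lo"] + max(1e-9, 1e-9 * abs(b["lo"]))
  }
  source_mm3 <- masked_volume_mm3(vol, mask)
  resampled <- reslice(vol, mask, profile)

  div_rows <- list()
  sum_rows <- list()
  for (n in as.integer(division_counts)) {
    p <- partition_range(b["lo"], b["hi"], n)
    lm <- build_label_map(vol, mask, p)
    per_div <- vector("list", n)
    for (i in seq_len(n)) {
      m <- withCallingHandlers(
        extract_mesh(lm, i),
        warning = function(w) invokeRestart("muffleWarning")
      )
      stl <- file.path(out_dir, sprintf("div_%d_%d.stl", n, i))
      write_stl(m, stl)
      per_div[[i]] <- dplyr::mutate(mesh_metrics(m, file.size(stl)),
                                    n_divisions = n, division = i,
                                    .before = 1)
    }
    per_div <- dplyr::bind_rows(per_div)
    div_rows[[as.character(n)]] <- per_div

    lut <- color_lut(p, blend_mode = blend_mode, blend_fraction = blend_fraction)
    stack <- colorize_stack(resampled, lut)
    png_dir <- file.path(out_dir, sprintf("png_n%d", n))
    png_man <- write_png_stack(stack, png_dir)
    sum_rows[[as.character(n)]] <- tibble::tibble(
      n_divisions = n,
      total_faces = sum(per_div$n_faces),
      total_vertices = sum(per_div$n_vertices),
      total_mesh_volume_mm3 = sum(per_div$enclosed_volume),
      total_components = sum(per_div$n_components),
      total_stl_bytes = sum(per_div$file_bytes),
      voxel_stack_bytes = attr(png_man, "total_bytes"),
      voxel_payload_bytes = attr(png_man, "raster_payload_bytes"),
      voxel_layers = length(stack$slices),
      voxel_volume_mm3 = stack_volume_mm3(stack),
      source_volume_mm3 = source_mm3,
      volume_loss_percent = 100 * (1 - sum(per_div$enclosed_volume) / source_mm3)
    )
  }
  report <- structure(list(
    divisions = dplyr::bind_rows(div_rows),
    summary = dplyr::bind_rows(sum_rows),
    source_volume_mm3 = source_mm3,
    out_dir = out_dir
  ), class = "comparison_report")
  utils::write.csv(report$divisions, file.path(out_dir, "mesh_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(out_dir, "comparison_summary.csv"),
                   row.names = FALSE)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  masked source volume: %.6g mm^3\n", x$source_volume_mm3))
  print(x$summary)
  invisible(x)
}

#' Per-division mesh metrics of a comparison report
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return The `divisions` tibble.
#' @export
tidy.comparison_report <- function(x, ...) x$divisions

#' Per-N summary of a comparison report
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return The `summary` tibble.
#' @export
glance.comparison_report <- function(x, ...) x$summary

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Four-panel audit plot for a comparison report
#'
#' Volume loss (%), total triangle count, total STL kilobytes and
#' disconnected shell count, each against the number of divisions, with the
#' voxel pipeline's PNG-stack kilobytes overlaid on the file-size panel.
#'
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @return A ggplot object (facetted).
#' @export
autoplot.comparison_report <- function(object, ...) {
  s <- object$summary
  long <- dplyr::bind_rows(
    tibble::tibble(n = s$n_divisions, metric = "volume lost (%)",
                   value = s$volume_loss_percent, series = "mesh (STL)"),
    tibble::tibble(n = s$n_divisions, metric = "mesh faces",
                   value = s$total_faces, series = "mesh (STL)"),
    tibble::tibble(n = s$n_divisions, metric = "file size (kB)",
                   value = s$total_stl_bytes / 1000, series = "mesh (STL)"),
    tibble::tibble(n = s$n_divisions, metric = "file size (kB)",
                   value = s$voxel_stack_bytes / 1000, series = "voxel (PNG)"),
    tibble::tibble(n = s$n_divisions, metric = "disconnected meshes",
                   value = s$total_components, series = "mesh (STL)")
  )
  long$metric <- factor(long$metric, levels = c(
    "volume lost (%)", "mesh faces", "file size (kB)", "disconnected meshes"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = unique(long$n)) +
    ggplot2::labs(x = "number of divisions", y = NULL, colour = NULL,
                  title = "Boundary-surface cost vs voxel pipeline") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Save the audit plot panels of a comparison report
#'
#' @param report A `comparison_report`.
#' @param path Output image path (PNG).
#' @return `path`, invisibly.
#' @export
plot_comparison <- function(report, path = file.path(report$out_dir, "comparison.png")) {
  g <- autoplot(report)
  ggplot2::ggsave(path, g, width = 8, height = 6, dpi = 120)
  invisible(path)
}
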