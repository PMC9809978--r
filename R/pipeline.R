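#' Assemble and validate a run configuration
#'
#' Configuration can come from a YAML/JSON file, a named list, or both
#' (explicit arguments override file values, which override defaults).
#'
#' Recognised keys: `input` (DICOM dir / NIfTI file), `mask` (NIfTI or PNG
#' stack dir), `phantom` (preset name, used when `input` is absent),
#' `window` (`center`, `width`), `n_divisions`, `division_counts`, `colors`,
#' `blend_mode`, `blend_fraction`, `dpi_x`, `dpi_y`, `layer_mm`,
#' `palette_file`, `material_mode`, `out_dir`, `seed`.
#'
#' @param config Path to a YAML/JSON config file, or a named list.
#' @param ... Individual overrides.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config = NULL, ...) {
  base <- list(input = NULL, mask = NULL, phantom = NULL, vol = NULL,
               window = NULL, n_divisions = 10L, division_counts = c(2L, 4L, 10L),
               colors = NULL, blend_mode = "linear", blend_fraction = 0.25,
               dpi_x = 600, dpi_y = 300, layer_mm = 0.027,
               palette_file = NULL, material_mode = "indexed_png",
               out_dir = NULL, seed = 17L)
  from_file <- list()
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file does not exist: ", config)
    from_file <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    from_file <- config
  }
  overrides <- list(...)
  cfg <- utils::modifyList(utils::modifyList(base, from_file), overrides)
  if (any(cfg$division_counts < 1) || cfg$n_divisions < 1) {
    stop_config("division counts must be >= 1")
  }
  for (p in c("input", "mask", "palette_file")) {
    if (is.character(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop_config(p, " path does not exist: ", cfg[[p]])
    }
  }
  structure(cfg, class = "run_config")
}

# Resolve the input volume + mask of a config: explicit in-memory objects,
# a file/directory path, or a named phantom preset.
resolve_input <- function(cfg) {
  if (!is.null(cfg$vol)) {
    vol <- cfg$vol
    mask <- if (!is.null(cfg$mask) && !is.character(cfg$mask)) {
      as_mask(cfg$mask, vol)
    } else if (is.character(cfg$mask)) {
      read_mask(cfg$mask, vol)
    } else {
      as_mask(array(TRUE, dim(vol$voxels)))
    }
    return(list(vol = vol, mask = mask))
  }
  if (!is.null(cfg$input)) {
    vol <- read_volume(cfg$input)
    mask <- if (!is.null(cfg$mask)) read_mask(cfg$mask, vol)
            else as_mask(array(TRUE, dim(vol$voxels)))
    return(list(vol = vol, mask = mask))
  }
  if (!is.null(cfg$phantom)) {
    ph <- generate_phantom(phantom_preset(cfg$phantom, seed = cfg$seed))
    return(list(vol = ph$vol, mask = ph$mask))
  }
  stop_config("config must provide one of: vol, input, phantom")
}

# Window the volume into the working [0, 1] domain: explicit window if
# given, else the full masked range.
working_volume <- function(vol, mask, window) {
  if (is.null(window)) {
    b <- compute_bounds(vol, mask)
    if (b["hi"] == b["lo"]) b["hi"] <- b["lo"] + 1
    window <- window_level(center = mean(b), width = diff(range(b)))
  } else if (!inherits(window, "window_level")) {
    window <- window_level(window$center, window$width)
  }
  apply_window_level(vol, window)
}

#' Run the full bitmap printing workflow
#'
#' Executes read -> window/level -> mask -> bounds -> partition -> LUT ->
#' reslice -> colorize -> PNG stack -> dither -> material stack, writing
#' every artifact under `out_dir` and recording paths, parameters and MD5
#' content hashes in `manifest.json`. Identical config + seed give identical
#' hashes.
#'
#' @param config A [run_config()], config file path, or named list.
#' @param ... Config overrides.
#' @return Tibble manifest (artifact, file, bytes, md5), invisibly the
#'   manifest path as attribute `manifest`.
#' @export
run_bitmap_pipeline <- function(config = NULL, ...) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config, ...)
  out_dir <- cfg$out_dir %||% file.path(tempdir(), "voxelprint_run")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop_io("cannot create directory ", out_dir)
  }
  inp <- resolve_input(cfg)
  wvol <- working_volume(inp$vol, inp$mask, cfg$window)
  b <- compute_bounds(wvol, inp$mask)
  if (b["hi"] <= b["lo"]) stop_data("masked intensity range is degenerate")
  p <- partition_range(b["lo"], b["hi"], cfg$n_divisions)
  lut <- color_lut(p, colors = cfg$colors, blend_mode = cfg$blend_mode,
                   blend_fraction = cfg$blend_fraction)
  lut_file <- file.path(out_dir, "lut.txt")
  write_lut(lut, lut_file)

  palette <- if (!is.null(cfg$palette_file)) {
    read_material_palette(cfg$palette_file)
  } else {
    default_material_palette()
  }
  profile <- printer_profile(cfg$dpi_x, cfg$dpi_y, cfg$layer_mm, palette)
  resampled <- reslice(wvol, inp$mask, profile)
  stack <- colorize_stack(resampled, lut)
  color_dir <- file.path(out_dir, "color_stack")
  color_man <- write_png_stack(stack, color_dir)
  mstack <- dither_stack(stack, palette)
  mat_dir <- file.path(out_dir, "material_stack")
  mat_man <- write_material_stack(mstack, mat_dir, mode = cfg$material_mode)

  artifacts <- tibble::tibble(
    artifact = c("lut",
                 rep("color_stack", nrow(color_man) + 1L),
                 rep("material_stack", nrow(mat_man) + 1L)),
    file = c(lut_file,
             file.path(color_dir, c(color_man$file, "manifest.json")),
             file.path(mat_dir, c(mat_man$file, "manifest.json")))
  )
  artifacts$bytes <- file.size(artifacts$file)
  artifacts$md5 <- unname(tools::md5sum(artifacts$file))
  rel <- artifacts
  rel$file <- substring(rel$file, nchar(out_dir) + 2L)  # paths relative to out_dir
  manifest <- list(
    parameters = list(
      n_divisions = cfg$n_divisions, blend_mode = cfg$blend_mode,
      blend_fraction = cfg$blend_fraction, dpi_x = cfg$dpi_x,
      dpi_y = cfg$dpi_y, layer_mm = cfg$layer_mm, seed = cfg$seed,
      bounds = as.list(b), materials = palette$names
    ),
    layers = length(stack$slices),
    voxel_volume_mm3 = stack_volume_mm3(stack),
    artifacts = rel
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  attr(artifacts, "manifest") <- manifest_path
  attr(artifacts, "voxel_volume_mm3") <- manifest$voxel_volume_mm3
  artifacts
}

#' Run the voxel-vs-mesh comparison study
#'
#' Invokes the mesh-based boundary-surface workflow and the voxel pipeline's
#' slicing on the same windowed, masked input for each configured division
#' count (default 2, 4 and 10) and writes the combined CSV report and audit
#' plot.
#'
#' @param config A [run_config()], config file path, or named list.
#' @param ... Config overrides.
#' @return A `comparison_report` (see [run_comparison()]).
#' @export
run_comparison_study <- function(config = NULL, ...) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config, ...)
  if (length(cfg$division_counts) == 0L) {
    stop_config("division_counts must not be empty")
  }
  out_dir <- cfg$out_dir %||% file.path(tempdir(), "voxelprint_study")
  inp <- resolve_input(cfg)
  wvol <- working_volume(inp$vol, inp$mask, cfg$window)
  palette <- if (!is.null(cfg$palette_file)) {
    read_material_palette(cfg$palette_file)
  } else {
    default_material_palette()
  }
  profile <- printer_profile(cfg$dpi_x, cfg$dpi_y, cfg$layer_mm, palette)
  report <- run_comparison(wvol, inp$mask,
                           division_counts = cfg$division_counts,
                           profile = profile, out_dir = out_dir,
                           blend_mode = cfg$blend_mode,
                           blend_fraction = cfg$blend_fraction)
  plot_comparison(report)
  report
}
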