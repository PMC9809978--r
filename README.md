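# voxelprint

Bitmap ("voxel") printing of volumetric medical images in R.

Soft tissue in MR and CT volumes carries hundreds to thousands of distinct
radiodensity values that vary gradually across an organ's interior. The
dominant 3D-printing route — threshold the volume into a few ranges, wrap
each range in a triangulated boundary surface (STL), print each shell as one
homogeneous material — cannot represent those gradients, and each added
threshold division costs triangles, file size and enclosed volume.
Material-jetting printers that accept per-layer raster bitmaps make the
surfaces unnecessary: every droplet position on every layer can be assigned
one of up to six resins directly from the imaging data.

`voxelprint` is for researchers and model-shop engineers preparing
patient-derived prints, and for anyone quantifying what the mesh route loses.
It implements:

* **the bitmap pipeline** — DICOM series / NIfTI ingestion, window/level
  normalisation to $[0,1]$, equal-width partition of the masked intensity
  range into $N$ divisions ($e_i = \ell + i\,(h-\ell)/N$), an RGBA lookup
  table with optional linear gradient blending between divisions,
  anisotropic trilinear resampling to the printer grid (600 x 300 DPI,
  0.027 mm layers by default), full-colour PNG slicing, and
  Floyd–Steinberg error diffusion (weights 7/16, 3/16, 5/16, 1/16,
  serpentine scan, linear-RGB nearest-palette metric) onto a six-material
  palette;
* **the mesh workflow and audit** — per-division threshold label maps,
  watertight iso-0.5 surface extraction, binary STL export, and the
  comparison report: faces, vertices, enclosed volume (divergence theorem),
  disconnected shells (shared-edge components) and bytes per division
  count, against the voxel pipeline's conserved volume,
  $100\,(1 - \sum_d V_d / V_{\mathrm{src}})$ volume loss;
* **synthetic phantoms** — nested-ellipsoid radiodensity volumes with
  analytic ground truth (exact $\tfrac{4}{3}\pi abc$ volumes, noise-free
  intensity functions), written as minimal DICOM series so the whole
  pipeline is testable without patient data.

## Worked example

Generate the gradient-sphere phantom (a 20 mm sphere whose intensity runs
200 at the centre to 800 at the surface, plus noise, on an anisotropic
0.8 x 0.8 x 3 mm grid), window it, and audit mesh divisions 2, 4, 10
against the voxel pipeline on a draft 0.4 x 0.4 x 0.5 mm printer grid:

```r
library(voxelprint)

ph <- generate_phantom(phantom_preset("gradient-sphere", seed = 17))
ph$vol
#> <image_volume> 62 x 62 x 20 voxels, spacing 0.8 x 0.8 x 3 mm
#>   intensity range [0, 853.635], origin (0, 0, 0) mm

b <- compute_bounds(ph$vol, ph$mask)
wvol <- apply_window_level(ph$vol, window_level(mean(b), diff(range(b))))
prof <- printer_profile(dpi_x = 25.4 / 0.4, dpi_y = 25.4 / 0.4, layer_mm = 0.5)
report <- run_comparison(wvol, ph$mask, division_counts = c(2, 4, 10),
                         profile = prof)
report
#> <comparison_report>
#>   masked source volume: 33500.2 mm^3
#> # A tibble: 3 x 12
#>   n_divisions total_faces total_vertices total_mesh_volume_mm3 total_components
#> 1           2       71248          35586                33454.               15
#> 2           4      146180          72918                33420.               35
#> 3          10      285860         140792                31000.              372
```

Reading the summary (`glance(report)`): as the division count rises
2 → 4 → 10, summed mesh volume falls from 33 454 to 31 000 mm³ (volume loss
0.14% → 7.5%) and triangle counts roughly quadruple, while the voxel
pipeline's alpha-carrying volume stays exactly at the 33 500 mm³ source
volume and its raster payload is identical for every N. `tidy(report)`
gives per-division metrics; `autoplot(report)` draws the four audit panels.

The printable output itself:

```r
stack  <- colorize_stack(reslice(wvol, ph$mask, prof),
                         color_lut(partition_range(0, 1, 10)))
mstack <- dither_stack(stack)                  # six-material error diffusion
material_fractions(mstack)
#> # A tibble: 6 x 3
#>   material  count fraction
#> 1 cyan     101635  0.243
#> 2 magenta   67593  0.161
#> 3 yellow   108716  0.260
#> 4 black    107726  0.257
#> 5 white     32331  0.0772
#> 6 clear       751  0.00179
write_material_stack(mstack, "print_job", mode = "per_material_bitmaps")
```

The fraction table is the resin budget of the job: which materials the
dithered deposition actually uses, summing to 1 over material-carrying
droplet positions.

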