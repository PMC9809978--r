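---
title: "Bitmap voxel printing of radiodensity volumes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bitmap voxel printing of radiodensity volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelprint)
```

## The problem

Clinical 3D printing for surgical planning overwhelmingly uses boundary
representations: an anatomy is segmented into a handful of threshold ranges,
each range is polygonised into a closed triangle mesh (STL), and every mesh
interior is printed as one homogeneous material. Soft tissue does not look
like that. A single MR or CT volume of a kidney, brain or heart carries
hundreds to thousands of distinct radiodensity values that vary gradually
across the organ's interior, and a surface-mesh pipeline must either collapse
them into a few solid shells or explode into thousands of mesh files.

Material-jetting ("PolyJet") printers remove the need for surfaces entirely:
they accept per-layer raster images in which every droplet position is
assigned one of up to six resins. `voxelprint` implements this bitmap
workflow end to end — scanner volume in, dithered printer-ready slice stack
out — together with the conventional mesh workflow and a quantitative audit
of what the mesh route costs (volume loss, triangle counts, file sizes,
disconnected shells).

## The bitmap pipeline

For a volume $I(\mathbf{x})$ with mask $M$, the stages are:

1. **Window/level.** $I' = \mathrm{clamp}\!\left(\frac{I - (c - w/2)}{w},\,
   0,\, 1\right)$ for window centre $c$ and width $w$. All later stages work
   in this normalised domain, decoupling them from scanner units.
2. **Bounds and partition.** With $[\ell, h]$ the masked intensity range,
   the partition has edges $e_i = \ell + i\,(h-\ell)/N$, $i = 0,\dots,N$:
   $N$ contiguous equal-width divisions with no overlap and no gap.
   Divisions are half-open $[e_i, e_{i+1})$ with the last closed, so every
   in-range value belongs to exactly one division. The printed-model studies
   use $N = 2, 4, 10$.
3. **Colour LUT.** Each division carries a target colour; between divisions
   the LUT can blend linearly over a band of width $\beta \cdot (h-\ell)/N$
   on each side of an interior edge ($\beta$ = `blend_fraction`, default
   0.25; $\beta = 0$ reproduces hard boundaries exactly). Blending is
   computed in linear-light RGB. Default `blend_mode` is `"linear"`, because
   the workflow this package implements deliberately builds smooth colour
   gradients between adjacent intensity regions.
4. **Reslice.** The scalar volume is resampled onto the printer's native
   grid — pitches $25.4/\mathrm{dpi}_x$ and $25.4/\mathrm{dpi}_y$ mm
   in-plane (0.0423 and 0.0847 mm at the default 600 x 300 DPI) and one
   layer per `layer_mm` (default 0.027 mm) — by trilinear interpolation;
   the mask is resampled nearest-neighbour. The scalar field is resampled
   *first* and the LUT applied pointwise *afterwards*: interpolating RGBA
   across division boundaries would blur the material identities that
   dithering must preserve.
5. **Colour slices.** One 8-bit RGBA PNG per layer; out-of-mask pixels have
   alpha 0 and mean "no material/support".
6. **Dithering.** Each slice is quantised to the material palette by
   Floyd-Steinberg error diffusion (below), giving per-pixel material
   assignments — the droplet deposition description the printer consumes.

### The error-diffusion model

Every pixel with alpha > 0 is assigned the palette entry nearest to its
error-adjusted colour in **linear-light RGB under Euclidean distance**, with
ties broken toward the lowest palette index. The quantisation error is pushed
to unprocessed neighbours with the classic weights 7/16 (ahead), 3/16
(behind-below), 5/16 (below), 1/16 (ahead-below), with rows scanned in
serpentine (boustrophedon) order to suppress directional worm artifacts.
Accumulated error is clamped to $[-1, 1]$ per channel before the nearest
search, which prevents runaway diffusion along mask boundaries. Alpha-0
pixels neither receive nor absorb error. There is no randomness anywhere in
the stage: identical input, palette and scan order give bit-identical
output, which is what makes the whole pipeline hash-stable.

Error diffusion preserves mean colour: over a uniform region whose target
lies in the palette's convex hull, the palette-weighted mean of the output
matches the target to well under 0.01 per linear-light channel (measured
~0.004 on 128 x 128 regions). Recovering *material fractions* is a subtly
different claim: six palette colours in three-dimensional colour space are
affinely dependent, so the barycentric representation of a target is not
unique — mid-gray, for instance, is exactly the clear resin's stand-in
colour as well as a black/white mixture. Fraction recovery is therefore only
well-posed for mixtures whose components are the uniquely nearest materials
all along the mixing segment; for the default palette that is the eight
pairs involving black or clear, and on those the recovered fractions match
the recipe to ~0.003. The package's tests assert fractions only on such
separable mixtures and mean colour everywhere.

### The material palette

The shipped palette models a six-resin machine: cyan, magenta, yellow,
black, white and clear. Exact resin colour coordinates are proprietary, so
nominal sRGB values are used (pure primaries plus `#D9D9D9` for clear — a
neutral light gray deliberately separated from white so the two stay
distinguishable dithering targets; process-ink CMY coordinates were
considered and rejected because they crowd the neutral axis and make most
mixtures ambiguous). Users override any of this via `material_palette()` or
a YAML palette file. For $N = 10$ divisions the LUT targets add red, orange,
green, blue and violet: non-material colours that the printer realises as
dithered mixtures of the six resins — no separate mixing table is needed.
Clear is a LUT *material*, not a LUT *target*, which is how ten apparent
colours arise from six resins.

## The mesh-based comparison workflow

The conventional route thresholds the same masked volume into the same $N$
ranges (`build_label_map()`, which is exactly the partition applied
voxel-wise), then polygonises each division's binary indicator
independently at iso-level 0.5 and exports binary STL. Key choices:

- **Isosurface extraction** uses marching tetrahedra on the Freudenthal
  (6-tetrahedra) decomposition of each grid cube, with vertices at
  midpoints of bipolar edges — the midpoint is the exact iso-0.5 crossing
  for a binary field. The decomposition is translation-consistent across
  cube faces, so the surface is watertight and consistently outward-oriented
  *by construction*, properties the volume audit depends on and which the
  tests verify directly (every extracted mesh has all edges shared by
  exactly two faces). Classic table-driven marching cubes produces the same
  class of surface; the tetrahedral variant was chosen because its
  correctness is provable from a dozen lines of case analysis rather than a
  4096-entry constant table. On a digitized 20 mm sphere at 0.5 mm voxels
  the enclosed volume is within 0.14% of $\tfrac{4}{3}\pi r^3$ and 0.02% of
  the voxel-count oracle.
- **No face sharing between divisions.** Each division is meshed from its
  own indicator with no morphological closing and no coincident-face
  enforcement. This deliberately reproduces the mechanism by which gaps
  open between adjacent threshold segments: each division's surface retreats
  half a voxel from the shared boundary, so summed enclosed volume falls as
  $N$ grows while the voxel pipeline's volume is conserved.
- **Enclosed volume** is the divergence-theorem sum of signed tetrahedron
  volumes to the origin (absolute value reported); open meshes are refused
  with a boundary-edge count rather than silently integrated.
- **Disconnected shells** are connected components of the face graph under
  shared-*edge* adjacency; vertex-only contact does not connect, matching
  the intuitive notion of separate shells. The count is invariant to face
  order and vertex numbering.
- **Volume loss** is reported against the masked source volume (voxel count
  x voxel volume): $100\,(1 - \sum_d V_d / V_{\mathrm{src}})$.

### What the audit shows, and on what

`run_comparison()` produces, per $N$: per-division faces, vertices,
enclosed volume, shell count and STL bytes; and for the voxel route the
PNG stack's on-disk bytes, its uncompressed raster payload
(layers x width x height x 4 bytes) and the alpha-carrying volume. On the
gradient-sphere phantom the summed mesh volume decreases strictly over
$N = 2 \to 4 \to 10$ and triangle counts and STL bytes grow strictly, while
the voxel volume stays within 1% of source (exactly equal when the printer
pitch divides the voxel pitch) and the raster payload is identical across
$N$. One honest caveat: the claim that voxel *file size* does not grow
with divisions is a statement about the printer's memory allocation,
i.e. the raster payload. Deflate-compressed PNG bytes on a
smooth low-entropy phantom *do* grow with $N$, because the colour path
length (and hence raster entropy) scales with the number of divisions;
real anatomies sit near the entropy ceiling where this effect vanishes.
The report carries both quantities so the distinction stays visible.

## Synthetic phantoms

`phantom_spec()` builds volumes from nested ellipsoids with exact analytic
volumes ($\tfrac{4}{3}\pi abc$), optional radial or axial intensity
gradients, and additive Gaussian noise applied in-mask. Defaults emulate
the features of clinical soft-tissue data that stress this pipeline:
anisotropic source voxels (0.8 x 0.8 x 3.0 mm), a wide intensity span
(hundreds of distinct values; the gradient-sphere preset runs 200 at the
centre to 800 at the surface), and noise at SNR ~ 25 (`noise_sd = 20`).
Generation is deterministic per seed; masks are geometry-only and thus
seed-invariant.

What the phantoms do *not* emulate: anatomical texture and fine structure
(they are geometric primitives), MR bias fields or Rician noise statistics,
partial-volume blur at tissue interfaces, and real-data entropy (see the
file-size caveat above). Passing tests on phantoms therefore demonstrate the
pipeline's geometric and radiometric fidelity — conservation, partition
exactness, dithering accuracy, mesh pathology reproduction — not robustness
to scanner artefacts.

## Numerical and interface choices

- Axis convention: arrays are indexed (x, y, slice); slice index increases
  with physical z. One fixed convention, stated everywhere, prevents silent
  flips.
- DICOM series: slices are ordered by physical position; inter-slice steps
  with relative spread up to $10^{-3}$ are accepted (scanner jitter) with
  the mean used as dz; a larger spread — e.g. a missing slice — is a
  geometry error reporting the observed step range.
- Degenerate inputs: a constant-intensity region widens its bounds by a
  token $10^{-9}$ so everything lands in division 1; an empty division
  yields an empty mesh with a warning; an empty masked region is an error.
- Writing: 16-bit unsigned DICOM with linear rescale (slope/intercept in
  metadata, mirroring CT/MR storage); binary STL (bytes = 84 + 50 per
  facet); indexed or per-material-bitmap PNG material stacks, both
  round-trip exactly.
- Problem sizes: the test-suite and acceptance computations use the
  gradient-sphere phantom at its default 0.8 x 0.8 x 3.0 mm grid (~62 x 62
  x 20 voxels) audited on a draft 0.4 x 0.4 x 0.5 mm printer grid, a 20 mm
  sphere digitized at 0.5 mm for the mesh oracle, and a 128^3 phantom for
  the end-to-end determinism run — sizes chosen so the whole suite
  exercises every stage at full fidelity in well under a coffee break.
- Exit codes of the `voxelprint` CLI: 0 success, 2 configuration error,
  3 data/geometry error, 4 I/O error.

## Known limitations

- Only window/level normalisation is implemented; no histogram equalisation
  or nonlinear display mapping.
- No ICC colour management, ink limiting, droplet-level calibration or
  optical model of clear-resin translucency: the clear material dithers as
  an ordinary colour.
- No mesh decimation or smoothing in the comparison workflow — deliberately,
  since either would confound the fidelity audit.
- The DICOM reader is scoped to the single-frame, explicit-VR-little-endian
  grayscale series the phantom writer emits (plus NIfTI for general input);
  it is not a general DICOM implementation.
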