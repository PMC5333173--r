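---
title: "coloc3d: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coloc3d: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coloc3d)
```

This vignette documents the scientific model behind `coloc3d`, the
conventions it fixes, the parameters that matter, what the synthetic
phantom does and does not emulate, and the design decisions that were
genuinely open.  It states no empirical result that the test suite does not
itself compute.

## Data model and coordinate conventions

A z-stack is stored as an `mc_stack`: co-registered per-channel
`voxel_grid`s, each a 3-D array of non-negative integers indexed
`(z, y, x)` with a bit depth (8 or 16) and an anisotropic voxel spacing
`(dz, dy, dx)` in micrometres.  Typical confocal acquisition steps the
focal plane in increments of about 0.4 µm while the lateral pixel pitch is
finer; when a file carries no spacing metadata the package assumes
`(0.4, 0.1, 0.1)` µm and warns, rather than failing, so downstream geometry
is always defined.  The lateral default is a plausible pitch, not a
measured one — supply the true spacing whenever it is known.

The world frame is **left-handed, y-up**: x points right (grid columns), y
up (grid rows), z away from the viewer (slice index).  TIFF files store
rows top-down; the flip between file row order and world y-up happens
exactly once, at I/O.  The volume occupies `[0, n*d]` along each axis with
voxel centers at `(i - 0.5) * d`.  **All indices in the R API are 1-based**,
the R-language convention; an early draft carried 0-based slice indices for
parity with array-oriented languages, but a mixed-base R API is an error
magnet and was rejected.

Intensities remain as-acquired integers; normalization to `[0, 1]`
(`normalize_intensity()`, division by `2^bits - 1`) is explicit, never
implicit, so thresholds can always be stated in native units.

## Colocalization metrics

A voxel is *colocalized* when it lies in the ROI and both channels fall
inside their `[low, high]` band.  Four conventions were open and are fixed
as follows:

- **Which thresholds feed which metric.**  The low threshold is a noise
  filter and applies to every metric; the high threshold participates only
  in the percentage metrics and the visual masks.  This keeps M1/M2, MOC
  and PCC comparable with the broader colocalization literature, where a
  single background cutoff is standard.
- **The considered set for MOC/PCC** is the union of above-low voxels of
  the two channels.  Intersection would condition the correlation on
  co-occurrence (inflating it toward the co-occurring subpopulation);
  using every ROI voxel would re-admit the background the noise filter is
  meant to remove.  The union keeps anti-correlated structure visible: a
  voxel bright in A and dark in B counts against the correlation, which is
  exactly what a correlation metric should see.  A practical consequence
  (visible in the README example) is that a phantom with half its blobs
  shared shows M1 near 0.5 but PCC well below 1.
- **Percentage colocalization is voxel-count based**, not
  intensity-weighted: `100 * n_coloc / n_a`.  The band definition fixes
  membership; counting is the simpler reading and makes the quantity an
  estimable binomial proportion, which the phantom recovery test exploits.
- **Empty denominators** (no voxel above threshold, constant channel)
  yield `NaN` plus an entry in the result's `undefined` field instead of an
  error, so batch runs over many ROIs degrade gracefully.

## Regions of interest

The ROI representation is deliberately the footprint-plus-depth model: a
2-D boolean footprint over `(y, x)` plus inclusive front/back slice
indices, the 3-D selection being the footprint extruded over that interval.
For tilted shapes this over-covers relative to true 3-D containment; the
extrusion is kept because it reproduces the published mask data structure
faithfully, and for the supported manipulations (axis-aligned scaling,
z-rotation, translation) it is exact.  Containment is tested at voxel
centers with the even-odd (crossing-number) rule for polygons —
deterministic and checkable against an exhaustive per-voxel oracle, which
the acceptance suite does on 32³ grids.

Shape transforms compose in parameter space (scales multiply per axis,
rotations compose, translations add, all about the shape center), the way
interactive manipulation handles behave, rather than as full affine matrix
composition; `scale_roi_axis()` therefore touches exactly one scale factor.
Freehand polygons are interpreted in the flattened, front-facing
orthographic view (the flattening step exists to avoid parallax during
drawing), so no perspective un-projection is attempted; the polygon is
auto-closed and the depth interval positioned afterwards by z scaling and
translation.

## Rendering

Three CPU renderers share one transfer function.  Per channel, normalized
intensity `i` below the channel's noise threshold maps to opacity 0;
otherwise `alpha_raw = i * channel_opacity * global_opacity` with color
`display_color * i`; channels merge per sample by over-compositing in
channel order.  The original interactive system exposes exactly these three
opacity controls but publishes no transfer function; this is the simplest
monotone mapping consistent with them, and it is convergence-tested rather
than assumed: opacity is corrected per sample as
`alpha = 1 - (1 - alpha_raw)^(dt / dt_ref)` with `dt_ref` the minimum voxel
spacing, so a homogeneous region has the exact closed-form pixel opacity
`1 - (1 - alpha_raw)^(L / dt_ref)` independent of step size, and renderings
converge as the step shrinks.

Numerical choices: rays pass through pixel centers of a perspective pinhole
camera (`right = up x view`, `up' = view x right`, left-handed); the ray
caster marches from box entry to exit with the per-ray step adjusted to
divide the traversal length evenly (this is what makes the closed form
exact); early termination triggers at accumulated alpha 0.99 by default;
defaults are `step = 0.5` times the minimum voxel spacing and
`slice_count = 2 *` the largest grid dimension.  The ray caster starts rays
on the bounding-box faces, so a camera inside the volume sees background —
the documented limitation of that mode; the slice renderer skips planes
behind the eye and keeps working from inside.  The pseudo-isosurface stops
at the first sample at or above `iso_value`, shades with the
central-difference gradient and a headlight Lambertian term, and multiplies
by the global opacity so that `global_opacity = 0` blanks every mode
uniformly.

## The synthetic phantom: what it emulates, and what a green test shows

`generate_phantom()` emulates the qualitative structure of a stained
fibroblast sample — compact fluorescent puncta on a dark background — as
isotropic Gaussian blobs (σ = 1.5 voxels by default, truncated at 3σ) on a
64³ 8-bit grid, 120 blobs per channel with peak amplitudes uniform in
[150, 230].  Co-occurrence is controlled by `overlap_fraction` (the shared
fraction of blob centers, deterministically `round(f * n)`), correlation by
a slope linking shared-blob amplitudes plus optional amplitude noise.
Ground truth is the set of voxels within 2σ of a shared center.

Two deliberate design choices make the phantom *analyzable*, not merely
realistic:

1. **Separation.**  Centers are drawn from a jittered lattice enforcing a
   minimum center distance of 5σ.  Combined with the 3σ truncation, no
   voxel inside one blob's 2σ truth region receives intensity from any
   other blob, so in-band membership is decided by a single blob
   everywhere that matters.
2. **Noise is opt-in.**  Default `noise_sd = 0` and exact slope-1 amplitude
   coupling make the channel-B field identical to channel A on shared blobs.
   Consequently the measured percentage colocalization equals the
   truth-mask percentage *exactly*, and the acceptance recovery criterion
   (agreement within 3 binomial σ across overlap levels, Spearman ρ = 1)
   tests the estimator rather than a noise model.  With additive noise the
   joint thresholding `A ≥ T and B ≥ T` systematically loses boundary
   voxels relative to the marginal count — a real effect of threshold-based
   colocalization, not a bug — so the noisy phantom is used for monotonicity
   checks (PCC rises with the correlation parameter) rather than exact
   recovery.

What the phantom does **not** emulate: the microscope point-spread function
(blobs are isotropic Gaussians, not PSF-convolved structures), Poisson
photon statistics, anisotropic blob shapes, intensity gradients with depth,
and the actual morphology of nuclei/mitochondrial networks.  A green
recovery test therefore establishes that the metric pipeline measures what
the generator encodes — not that any particular biological sample would be
measured without bias.

## Contingency statistics

Subjective 5-point ratings concentrate at the top of the scale; levels 1-3
are pooled before testing so expected cell counts stay defensible.  The
Yates continuity correction is applied per cell, with the corrected
deviation floored at zero, for any table size — including df = 2 tables,
where its use is unconventional but deliberate here; the uncorrected
statistic is also available internally and the large-count invariance tests
are formulated against it.  Cramér's `V = sqrt(chi2 / (N (k - 1)))` takes
`N` as the total count of the analyzed table and `k` as the lesser
dimension, both exposed explicitly in `chi2_report()` so either pooling
convention for `N` can be computed by the caller.  A known loose end in the
source material — the claim that V ≈ 0.4 corresponds to p = 0.05 at df = 2,
which is not exactly reproducible under either plausible `N` — is
documented here and asserted nowhere.

## File formats and limitations

TIFF support is a minimal, self-contained baseline codec (uncompressed
grayscale 8/16-bit multi-page, both byte orders on read, spacing and
channel layout in the ImageDescription); it exists because no TIFF package
is available in the supported dependency set, and it is cross-validated in
the test suite against an independent Python reader/writer.  Compressed,
tiled, color or floating-point TIFFs are out of scope, as are OME-XML and
vendor formats.  PNG output is an equally minimal 8-bit encoder.  Other
known limitations: no Costes threshold estimation or randomization tests,
no deconvolution or registration, no GPU path, and rendering is sized for
figure generation, not interactive frame rates.
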