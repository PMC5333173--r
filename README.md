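# coloc3d

Headless volume rendering and quantitative colocalization analysis for
multi-channel confocal z-stacks, in pure R.

## Who this is for

Confocal microscopes produce z-stacks: series of 2-D fluorescence images at
successive focal depths that together form a 3-D, multi-channel volume.  A
recurring analysis question is **colocalization** — do two fluorescent probes
occupy the same structures (co-occurrence), and do their intensities
codistribute proportionally (correlation)?  Interactive viewers answer this
visually; `coloc3d` provides the same computational core as a scriptable,
display-free toolkit: stack I/O, region-of-interest (ROI) selection,
threshold-based colocalization metrics, the standard colocalization
visualizations, and CPU volume rendering for figure generation — plus a
synthetic phantom generator with known ground truth so every stage can be
validated without microscope data.

## The statistics at the core

All metrics are computed over an ROI, under per-channel low/high intensity
thresholds.  The **low threshold acts as a noise filter** and is the only
threshold used by the intensity-weighted metrics; the high threshold enters
the voxel-count metrics and the visual masks.  With voxel intensities
$A_i, B_i$:

- **Manders' colocalization coefficients**
  $M_1 = \dfrac{\sum_{A_i \ge T_A,\, B_i \ge T_B} A_i}{\sum_{A_i \ge T_A} A_i}$,
  and $M_2$ with channels swapped.
- **Manders' overlap coefficient**
  $\mathrm{MOC} = \dfrac{\sum A_i B_i}{\sqrt{\sum A_i^2 \sum B_i^2}}$
  over voxels above the low threshold in either channel.
- **Pearson's correlation** of $(A_i, B_i)$ over the same set.
- **Percentage colocalization**: the share of in-band voxels of one channel
  whose partner is also in band,
  $100 \cdot n_\mathrm{coloc} / n_A$.

For rating-scale data the package also implements the contingency-table
pipeline: 5-to-3 rating grouping, the per-cell Yates-corrected
$\chi^2 = \sum (\,|O - E| - 0.5\,)^2 / E$, its upper-tail p-value, and
Cramér's effect size $V = \sqrt{\chi^2 / (N(k-1))}$ with $k$ the lesser
table dimension.

ROIs follow the footprint-plus-depth model: rasterizing a box, cylinder or
freehand polygon yields a 2-D boolean footprint over (y, x) plus inclusive
front/back z slice indices; the selected voxels are the footprint extruded
over that interval.

The renderer offers three modes sharing one transfer function (noise
threshold, global and per-channel opacity): perspective **ray casting**
(front-to-back compositing with early termination; renders from the bounding
box faces, so it blanks when the camera enters the volume),
**view-aligned slices** (back-to-front proxy planes; still works from inside
the volume), and a **pseudo-isosurface** (first-hit ray casting with
gradient Lambertian shading).

## Worked example

```r
library(coloc3d)

# a 64^3, 2-channel phantom: 120 Gaussian blobs per channel, half the blob
# centers shared between the channels
ph <- generate_phantom(phantom_spec(overlap_fraction = 0.5, seed = 11))
st <- ph$stack

# restrict to a cylindrical ROI and quantify colocalization above noise
roi <- rasterize_roi(scale_roi_axis(make_cylinder_roi(st), "z", 0.8), st)
coloc_report(st, coloc_params(1, 2, low_a = 50, low_b = 50), roi)
```

```
<coloc_result>
  M1 = 0.4964  M2 = 0.4939  MOC = 0.5010  PCC = -0.1751
  pct_a = 49.22%  pct_b = 48.84%  (n_coloc 3013, n_a 6122, n_b 6169, |S| 9278)
```

About half of each channel's above-threshold signal sits where the other
channel is also above threshold — matching the generating truth
(`overlap_fraction = 0.5`): with half the blob centers shared, roughly half
the in-band voxels of each channel are genuinely co-occurring.  The modest
PCC is expected too: it is computed over the union of above-threshold
voxels, where the non-shared blobs (bright in one channel, dark in the
other) pull the correlation down even when the shared blobs are perfectly
coupled.  The measured percentage can be checked against the ground-truth
mask with `phantom_truth_pct(st, ph$truth, 1, low = 50)` (50.02% here on
the full volume), which equals the full-volume measured percentage exactly
in the default noise-free world.

Render a figure:

```r
ext <- stack_extent(st)
cam <- camera(position = c(ext[1]/2, ext[2]/2, -2 * ext[3]),
              look_at = ext / 2, fov = 35, width = 256, height = 256)
img <- render_raycast(st, cam, render_settings(noise_low = 50 / 255))
write_png(img[, , 1:3], "phantom.png")
```

Command line (same operations, scriptable):

```sh
Rscript inst/scripts/coloc3d synth --spec spec.json --out phantom.tif --truth truth.json
Rscript inst/scripts/coloc3d coloc run --stack phantom.tif --ch-a 1 --ch-b 2 \
    --low 50,50 --out report.csv --scatter scatter.png
Rscript inst/scripts/coloc3d stats chi2 --table ratings.csv
```

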