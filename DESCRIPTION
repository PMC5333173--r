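Package: coloc3d
Title: Headless Volume Rendering and Colocalization Analysis for Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("coloc3d", "maintainers", email = "coloc3d@example.org", role = c("aut", "cre"))
Description: Tools for quantitative colocalization analysis of multi-channel
    confocal z-stacks without a graphical front end. Reads and writes
    multi-page TIFF stacks, rasterizes box, cylinder and freehand regions of
    interest into a 2-D footprint plus z-interval mask, computes threshold-based
    colocalization metrics (Manders' M1/M2, Manders' overlap coefficient,
    Pearson's correlation, percentage colocalization) together with the
    standard colocalization visualizations (white-voxel overlays and
    pseudo-colored intensity scatter plots), and renders volumes on the CPU by
    ray casting, view-aligned slice compositing or pseudo-isosurface shading.
    Also includes a synthetic phantom generator with known ground truth and
    contingency-table statistics (Yates-corrected chi-square, Cramer's V) for
    rating data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
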