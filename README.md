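# axofoci

Quantification of meiotic DSB-protein foci relative to chromosome axes
in multi-channel 3D fluorescence z-stacks.

During meiotic prophase I, DSB-forming proteins such as SPO11-1 appear
as thousands of punctate immunofluorescence foci, while axial elements
(DSY2-labelled; ZYP1 where synapsed) form a tangle of curvilinear tubes.
`axofoci` turns those stacks into per-nucleus numbers:

* **Foci** — seeded 3D spot segmentation after histogram-based
  thresholding (`mode + k·1.4826·MAD` of the background peak's reflected
  lower tail), rolling-ball background subtraction and 3D median
  filtering, with per-object measurements (centroid `CX, CY, CZ`,
  volume, sphericity `Comp = 36πV²/S³`, centre-to-border distances
  `DC`, intensity `AtCenter`/`IntDen`/`Min`/`Mean`).
* **Axes** — top-hat filtering, trainable voxel classification (or an
  Otsu threshold fallback), Hessian tubeness (`σ²·√(λ₂λ₃)` for
  λ₂, λ₃ < 0), topology-preserving 3D thinning to medial lines, spur
  pruning and branch tracing.
* **Focus–axis geometry** — an exact anisotropic 3D Euclidean distance
  transform from the skeleton; a focus is *axis-associated* exactly
  when its minimal distance is zero, i.e. its voxel mask overlaps a
  skeleton voxel (no tolerance).
* **Axis metrics** — total skeleton length (µm/mm), curvature by local
  circle fitting (κ = 1/r, 7-point windows), and the synapsis
  percentage (100 × ZYP1 length / DSY2 length).
* **Ground truth** — a synthetic-nucleus simulator (tortuous axes in a
  spherical nucleus with a nucleolar exclusion zone, a configurable
  chromatin-sleeve distance distribution for off-axis foci, shot and
  read noise, 16-bit quantization) so every stage is verifiable without
  microscopy data.

All tabular results are tibbles; images are light S3 wrappers around 3D
arrays with physical voxel spacing.

## Worked example

```r
library(axofoci)

cfg <- pipeline_config(
  simulate = list(grid_shape = c(64, 128, 128),
                  voxel_spacing = c(0.125, 0.08, 0.08), nucleus_radius = 3.8,
                  nucleolus_radius = 1, nucleolus_center = c(0, 1.5, 0),
                  n_axes = 3, axis_total_length = 60, n_foci_total = 200,
                  n_foci_axis_touching = 20,
                  offaxis_distance_distribution =
                    list(name = "uniform", min = 0.25, max = 2.2),
                  focus_sigma = 0.07, focus_axial_ratio = 2, seed = 44),
  seed = 44)
res <- run_pipeline(cfg, out_dir = "demo_out")
res$summary
#> # A tibble: 1 x 8
#>   cell_id stage_label n_foci_total n_foci_axis_associated axis_total_length_um
#>   <chr>   <chr>              <int>                  <int>                <dbl>
#> 1 cell1   ""                   181                     17                 65.7
#> # i 3 more variables: axis_total_length_mm <dbl>, percent_synapsed <dbl>,
#> #   median_kappa <dbl>
res$distance_distribution
#> <dist_distribution> n = 181, median 0.599 um, 50.3% within 0.6 um
```

181 segmented foci for 200 planted (close pairs below the diffraction
limit merge), 17 of them axis-associated for 20 planted on-axis, and
65.7 µm of skeletonized axis for 60 µm of generated path;
`res$objects` holds the per-focus table (geometry,
intensities, `dist_min_um`, `is_axis_associated`),
`res$distance_distribution` the distance histogram with its median, and
`res$skeleton` the traced axis model
(`skeleton_total_length()`, `branch_curvatures()`,
`plot_distance_distribution()` work from there). Real stacks enter the
same pipeline through the `input` block (multi-page 16-bit TIFFs plus
voxel spacing) instead of `simulate`. A thin command-line wrapper for
each stage lives at `inst/cli/axofoci.R`.

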