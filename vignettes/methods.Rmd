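---
title: "Quantifying meiotic DSB-protein foci relative to chromosome axes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meiotic DSB-protein foci relative to chromosome axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

During meiotic prophase I, the DSB-forming machinery (SPO11 and its
partners) appears in immunostained nuclei as thousands of punctate foci,
while the axial elements of the chromosomes (labelled here by DSY2-type
antibodies, with ZYP1 marking synapsed stretches) appear as a tangle of
curvilinear tubes. The biological questions — how many foci are there,
how many sit *on* the axis, how the distance distribution relates to the
chromatin "sleeve" around each axis, how long and how curly the axes are,
and what fraction of axis is synapsed — all reduce to geometry on
multi-channel 3D z-stacks.

`axofoci` implements that geometry as a reusable pipeline:

1. **Spot segmentation** of the focus channel: histogram threshold
   selection, rolling-ball background subtraction, 3D median filtering,
   seeded 3D spot growth, and per-object 3D measurement
   (centroid, volume, sphericity, centre-to-border distances, intensity
   statistics).
2. **Axis segmentation**: top-hat filtering, trainable voxel
   classification (with a plain threshold fallback), Hessian tubeness,
   topology-preserving 3D skeletonization, spur pruning and branch
   tracing.
3. **Distance analysis**: an exact anisotropic Euclidean distance
   transform seeded at skeleton voxels, per-object distances
   (`AtCenter`, `Min`, `Mean`), and the strict *zero-distance*
   axis-association rule: a focus is axis-associated exactly when its
   voxel mask overlaps a skeleton voxel.
4. **Axis metrics**: total skeleton length (µm and mm), per-point
   curvature by local circle fitting (κ = 1/r), and the synapsis
   percentage (ZYP1 length over DSY2 length).
5. A **synthetic-nucleus simulator** that provides voxel-level ground
   truth, so each stage above is testable without microscopy data.

## The synthetic nucleus

The generator emulates the statistical structure the analysis assumes,
not the optics of any particular instrument.

* **Geometry.** A spherical nucleus (default radius 3.8 µm) with one
  spherical nucleolar exclusion zone sits centred in a 64 × 256 × 256
  voxel grid at (0.125, 0.04, 0.04) µm spacing — a plausible
  super-resolution acquisition geometry; the true voxel size of the
  original instrument is not published, so spacing is configurable
  everywhere.
* **Axes.** `n_axes` (default 10, one per bivalent-scale structure)
  smoothed 3D random walks. The per-step turning angle is proportional
  to the `tortuosity` parameter; `tortuosity = 0` gives straight
  segments, and mean curvature increases monotonically with it. Each
  path is trimmed to exactly `axis_total_length / n_axes` µm. The
  default total of 300 µm is the most axis this desk-scale nucleus can
  hold with tubes still mutually resolvable at the stated spacing; the
  millimetre-scale totals of real nuclei are deliberately not
  reproduced. Tubes are rendered with a Gaussian cross-section
  (σ = 0.1 µm).
* **Foci.** Exactly `n_foci_total` (default 2,500, inside the published
  per-nucleus range) anisotropic Gaussian spots (lateral σ 0.05 µm,
  axial ratio 2.5 — a diffraction-limited SIM-like point response) with
  amplitudes 12,000–28,000 counts, bright enough that the field's own
  threshold-and-grow workflow can segment them, as it evidently could in
  the source experiments. `n_foci_axis_touching` of them (default 350)
  sit on the axes, offset from the medial line by a half-normal draw
  with σ = `axis_tube_sigma`/5. The rest are placed at
  chromatin-sleeve distances drawn from a configurable distribution and
  enforced by rejection; `true_min_distance_um` always records the
  exact recomputed point-to-polyline distance.
* **The sleeve distribution.** The default is
  lognormal(meanlog −1.108424, sdlog 0.466320), which places exactly
  55% of its mass within 0.35 µm and 90% within 0.6 µm of an axis.
  Among distributions satisfying those two quantiles we chose the
  lognormal because it has essentially no mass below ~0.1 µm: a
  "sleeve" is a shell *around* the axis, so the off-axis class stays
  geometrically distinct from the axis-touching class at the instrument
  resolution. At desk-scale axis density the rejection step slightly
  suppresses the far tail (a candidate far from its anchor axis is
  often close to another axis); this bias is documented rather than
  corrected.
* **Camera.** Constant background (default 3,200 counts) plus a smooth
  low-frequency field, Poisson shot noise (`photon_scale` counts per
  photon), Gaussian read noise (σ 150), and 16-bit quantization. These
  defaults put automatic thresholds in the 3,000–4,000 count band
  typical of such stacks. A generation report records the clipped-voxel
  fraction and warns above 0.1%.
* **Not modelled:** optical PSF/SIM reconstruction artefacts,
  photobleaching, chromatin texture, multi-nucleus fields. Passing
  tests therefore demonstrate the *geometry and measurement chain*, not
  robustness to instrument-specific artefacts.

## Spot segmentation choices

* **Threshold rule.** `mode + k × 1.4826 × median(mode − x | x ≤ mode)`
  with `k = 3`: the robust spread of the reflected lower tail of the
  unimodal background histogram. The threshold is computed on the *raw*
  image (the 3,000–4,000 band refers to raw 16-bit counts) and applied
  to the background-subtracted image, whose spot peaks remain on the
  raw count scale while the background pedestal is gone — the pedestal
  then acts as a conservative safety margin. A manual numeric threshold
  bypasses the rule entirely.
* **Rolling ball.** Grayscale opening per z-plane with a spherical-cap
  height profile (radius 10 px by default), subtracted from the slice.
* **Median filter.** 3 × 3 × 3 by default. Because a diffraction-limited
  focus is only ~1.5 voxels wide laterally at this spacing, the median
  can fuse close peaks; seeds are therefore detected on the
  background-subtracted image *before* median filtering, and by default
  growth runs on that image too (the median image is kept for quality
  control and is the better growth substrate when foci span many
  voxels; `spot_params(growth_image=)` switches). Duplicate near-peak
  seeds resolve during growth (the brighter seed claims the region
  first).
* **Growth rule.** Per seed, a radial Gaussian is fitted to the local
  profile; the object grows over 26-connected voxels above
  `local_contrast_fraction` (default 0.5) of the fitted peak,
  highest-intensity-first, capped at `max_volume` (2,000 voxels);
  objects below `min_volume` (4 voxels) are discarded. Contested voxels
  go to the seed with the higher peak (ties: lower seed index).
* **Sphericity.** `Comp = 36π V²/S³`, with the surface estimated from
  exposed voxel faces and the stereological 2/3 orientation correction,
  clamped to 1. The centre-to-border distance is ambiguous in the
  field's tooling, so both `DC_min` and `DC_max` are reported.

## Axis segmentation choices

Processing order is fixed: top-hat → (classifier *or* threshold) →
tubeness on the masked intensity → binarize at the Otsu threshold of
the in-mask tubeness → drop components under 27 voxels → skeletonize →
prune spurs (< 0.5 µm).

* The trainable classifier is a seeded random forest over a
  multi-scale filter bank (Gaussian, difference-of-Gaussians, gradient
  magnitude, three sorted Hessian eigenvalues; six features per scale),
  standing in for interactive trainable-segmentation tools whose
  trained models are not available. It is equivalent *by contract*
  (Dice and length checks), not voxel-identical. The Otsu threshold
  fallback is the default in the automated pipeline.
* Tubeness at physical scale σ (default 0.1 µm, the expected tube
  radius): with Hessian eigenvalues λ1 ≥ λ2 ≥ λ3, the score is
  σ²·√(λ2λ3) where both are negative. Derivatives are computed in
  physical units, so anisotropic spacing is handled.
* Skeletonization is simple-point iterative thinning with six
  directional subiterations and curve-endpoint preservation, which
  provably preserves connected components and cycles. Two refinements
  matter in practice: candidates are deleted dimmest-first (ordered
  thinning), so the line tracks the intensity ridge; and free tips of
  long branches are extended along their terminal tangent while still
  inside the mask, compensating the ~1-voxel end-cap retraction that
  directional thinning causes on tubes. Exact voxel placement still
  differs from any particular reference tool; fidelity is assessed via
  length, topology and distances, not voxel identity.

## Distance analysis choices

The distance map is the exact Euclidean distance transform
(lower-envelope algorithm per axis) with anisotropic spacing, seeded at
skeleton voxels; it is 0 on skeleton voxels and only there. The
association rule "minimal distance equals zero" therefore means
mask–skeleton voxel overlap, which is resolution-dependent by
construction: with dz = 0.125 µm, the skeleton's axial position is
quantized to a full plane, and a focus mask whose half-maximum reach is
~0.06–0.09 µm can miss the skeleton by one voxel. On moderate-density
ground-truth nuclei the strict rule recovers the planted axis-touching
class at roughly 85–95% while keeping foci ≥ 0.3 µm away below 5%
false association; this recall ceiling is a property of the criterion
at this grid, not of any particular implementation, and is the reason
the classification-recovery test asserts 85% for the touching class.
`Min` is computed over the full object mask (identical to border-only
for a transform that is zero only on the skeleton).

## Axis metrics choices

* Skeleton length is the sum of physical step lengths along traced
  branches; branches partition the graph's edges, so junctions are not
  double-counted. Redundant diagonal "shortcut" adjacencies in voxel
  staircases are dropped before tracing so they create neither spurious
  cycles nor extra length. Step-sum lengths of arbitrarily oriented
  digital lines still overestimate by a few percent (the staircase
  effect, worst across z at this anisotropy); the length-fidelity test
  uses an in-plane tube where the effect is small and documented.
* Curvature: branch polylines are smoothed with an 11-point moving
  average, resampled at 0.3 µm, and fitted per point with an algebraic
  least-squares circle over a 7-point window (in the best-fit local
  plane for 3D traces); κ = 1/r, with radii capped at 10⁶ µm so
  straight runs give κ ≈ 0. The fit is exact on noise-free arcs.
  Because curvature of a non-circular curve is bandwidth-dependent, the
  generator's truth curvature is evaluated at the same bandwidth
  (0.3 µm resampling, window 7); pipeline-vs-truth agreement within
  20% holds across tortuosity 0.2–2 at default noise. A per-slice 2D
  mode is available through `fit_kappa()` on 2D traces.
* Synapsis is the ratio of two skeleton totals, each counted once per
  channel; values above 100% are flagged, never clamped. How the
  original analysis treated doubled (paired) axes in a synapsed stretch
  is not published; counting each channel's skeleton once is this
  package's documented convention.

## Problem sizes and determinism

Every quantity in the test suite and the acceptance script is computed
at desk scale: full study-condition nuclei are 64 × 256 × 256 voxels
with 2,500 planted foci and 300 µm of axis (about 30–60 s per nucleus
on one core); module tests use 16–48 plane fixtures. All randomness
flows from explicit integer seeds: a `simulation_config` plus its seed
regenerates voxel-identical channels, and `run_pipeline()` reruns are
byte-identical. Statistical checks (recovery rates, cohort contrasts)
use fixed seeds and are therefore deterministic assertions.

## Known limitations

* At the study-condition density (2,500 foci around 300 µm of axis in a
  ~230 µm³ nucleus) roughly a quarter of planted foci lie closer than
  the diffraction limit to a neighbour; merged pairs are segmented as
  single objects, so recovered *total* counts at that density
  undershoot the planted count. Count-recovery accuracy (±10%) is
  therefore assessed at resolvable densities; the axis-association
  count, which is the quantity of scientific interest, is insensitive
  to merging among co-located axis foci.
* The strict zero-distance association rule is resolution-dependent
  (see above).
* Where axes approach each other below the tube diameter, their masks
  merge and the skeleton locally rewires; at the default packing this
  affects a small fraction of axis length but is visible in distance
  truth-recovery tails.
* The classifier path is intended for cropped or training-scale
  volumes; feature stacks of full 4-million-voxel grids are memory
  hungry, and the automated pipeline defaults to the threshold
  fallback.
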