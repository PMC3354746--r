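---
title: "Segmenting the breast skin in T2 MRI: method and design notes"
author: "mammoskin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the breast skin in T2 MRI: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammoskin)
```

## The problem

On axial T2 turbo-spin-echo breast MRI, fat is bright while both the skin
and the fibroglandular ("dense") tissue are dark, with closely overlapping
intensity distributions. Any intensity-only segmentation therefore confuses
the thin (1–3 mm) skin shell with internal dense tissue. That confusion
matters twice: breast-density estimates are biased when skin voxels pollute
the dense cluster, and biomechanical models of mammographic compression
behave measurably differently when the skin is modelled as its real
segmented geometry rather than the classical uniform 2D membrane.

`mammoskin` implements a staged pipeline that separates the skin
geometrically rather than by intensity alone, a synthetic phantom that makes
every stage testable without clinical data, and the small biomechanical
toolbox used to quantify the membrane approximation error (the neo-Hookean
strain-energy form and the committed-error metric on plate reaction forces).

## The pipeline

`run_pipeline()` executes the stages below in order, per breast, and logs
every parameter and per-class voxel count. All defaults reproduce the
method's published operating point.

1. **Breast/axial separation** (`split_breasts()`). The frontier is the
   lowest (most posterior) point of the inter-breast cleavage with a high
   gray-level variation, aggregated over all slices. Operationally: forward-
   difference gradient magnitudes are averaged over slices; within the
   central third of columns, each column is scanned anterior to posterior
   for its first high-gradient row, and the deepest such column wins (ties
   break toward the band center). "High" means above the 90th percentile of
   the band *and* above half the band maximum — a fixed percentile alone
   would always flag 10% of pixels, including pure noise posterior to the
   real cleavage, so the half-maximum floor is what makes the rule robust.
   Rows posterior to the frontier are the axial zone and are cropped;
   columns on the far side of the frontier are zeroed.
2. **Curvature flow** (`curvature_flow()`, `time_step = 0.0625`,
   `iterations = 10`). Explicit 3D integration of `I_t = kappa * |grad I|`:
   every iso-intensity contour moves with speed proportional to its mean
   curvature, so small noise structures vanish quickly while large
   interfaces barely move. The iteration count is honoured exactly (no
   auto-convergence): more iterations only trade boundary fidelity for
   smoothness at linear cost. Finite differences are spacing-aware with
   replicated borders, and each update is clamped to the input's range so
   the discrete scheme satisfies the max principle exactly (the clamp is the
   standard stabilisation of the explicit scheme; on realistic volumes it
   almost never binds).
3. **Low threshold** (`low_threshold()`, `level_255 = 6`). Residual
   background structures grouped at low gray values are zeroed at
   `min + (6/255) * (max - min)` of the volume's own range — the classical
   "6 of 255" cut expressed scale-freely, hence valid for 16-bit data. The
   operation is idempotent.
4. **4-cluster C-means** (`partition_4()`). Hard C-means on all voxel
   intensities. Sorted by mean: the darkest cluster is background (plus the
   darkest dense voxels), the brightest is fat, and the two middle clusters
   are the `MIXED` transient class where skin and dense tissue live.
5. **Re-clustering of the mixed voxels** (`recluster_mixed()`). A fresh
   2-cluster C-means over the mixed voxels only, reading their intensities
   from the *original* volume. This detail is load-bearing: smoothing
   creates a halo of intermediate intensities in the air hugging the skin,
   and those voxels are ambiguous after filtering but plainly background in
   the original. By default the darker sub-cluster is merged to background
   when its original mean is background-like ("an image with a
   differentiated background"); both alternatives are available via
   `mapping =`. All remaining candidates become `DENSE` — at this point
   "dense" means *dark tissue candidate*, and geometry, not intensity,
   decides which candidates are skin.
6. **Largest object** (`largest_foreground()`): the biggest 3D connected
   component of non-background voxels is the breast; everything else is
   background. Ties break toward the component containing the smallest
   linear voxel index.
7. **Open–close** (`open_close()`): per-slice binary opening then closing
   with a 3×3 square element smooths the breast border; voxels added by
   closing take their majority neighbour label.
8. **Skin/dense separation** (`separate_skin_dense()`). First, background
   pockets enclosed by the breast (dark dense voxels that fell into the
   background cluster) rejoin the candidates — every pixel between the skin
   limits belongs to a tissue class. Only background connected to the
   anterior or lateral image borders counts as exterior: the posterior
   border of a breast ROI is the chest cut, not air. Then, per slice, the
   search marches inward from the breast boundary through contiguous
   candidate voxels; candidates reached before the first fat voxel become
   skin. Inside the nipple band — the anterior `nipple_band_fraction`
   (default 0.15) of the breast's per-slice extent, the one region where
   skin and dense tissue may be in physical contact — the march is capped at
   `ceiling(max_depth_mm / in-plane spacing)` voxel steps (3 mm default,
   ceiling so a physically 3 mm layer is never under-segmented). Candidate
   pockets enclosed by skin alone are closed to skin; everything else stays
   dense. A `global_depth_limit` flag applies the cap everywhere for users
   who prefer the conservative reading.
9. **Artifact filters**. `absorb_isolated_dense()` passes single-pixel
   dense components touching the skin to the skin.
   `interior_smoothness()` iteratively relabels any skin voxel with at
   least 3 of its 4 in-plane neighbours outside the skin class (and any
   dense voxel in skin contact with at least 3 of 4 non-dense neighbours)
   to the majority neighbour class, with deterministic tie preferences
   (fat over background over dense when removing skin; skin over fat over
   background when removing dense), synchronously, to a fixpoint. This
   removes the one-voxel-thick filaments and spurs the separation can leave.
10. **3D skin closure** (`close_skin_3d()`). A per-slice segmentation leaves
    the 3D reconstruction with inter-slice holes; any fat or dense voxel
    3D-adjacent (6-connectivity default) to background becomes skin,
    iteratively, until no internal tissue touches background. Out-of-volume
    neighbours are not background, so crops do not trigger closure. The
    resulting invariant — zero internal-tissue voxels adjacent to
    background — is the module's defining postcondition and is asserted on
    every phantom in the test suite.
11. **Skin removal and tissue segmentation**. The skin mask deletes the
    skin from the original volume (`apply_skin_mask()`), and a final
    2-cluster C-means on the remaining breast voxels separates fat (bright)
    from dense (dark) (`segment_fat_dense()`), yielding the density report.

A fixed-thickness baseline mode (`fixed_thickness_mm` in
`pipeline_config()`) replaces stage 8 with a uniform shell measured inward
from the boundary — the classical approach this method replaces. On breasts
with 1 mm true skin it labels roughly the shell-to-skin thickness ratio more
voxels as skin; the acceptance suite asserts the inequality.

## Clustering model

C-means here is the hard-membership partition minimising the within-cluster
sum of squared errors: `x` joins cluster `j` whenever
`||x - m_j||^2 < ||x - m_i||^2`, alternated with the mean update until no
assignment changes (Lloyd iteration), in the 1-D intensity feature space.
Initialisation is deterministic quantile seeding (centers at the
`(2i-1)/(2k)` quantiles) so runs are reproducible; because a single Lloyd
start on very small samples is prone to local optima, small problems
(n ≤ 10 000) add nine seeded random restarts and keep the best SSE, while
volume-scale runs use the single deterministic start. An emptied cluster is
re-seeded at the point farthest from its center. SSE is non-increasing
across sweeps (recorded in `sse_trace` and asserted in tests), and the
1-D optimum is cross-checked against exhaustive contiguous-split search —
1-D optimal clusters are intervals — on hundreds of random small samples.

## The phantom

`make_breast_phantom()` emulates what the pipeline needs from an axial T2
acquisition and nothing more: two spherical breasts partially submerged in a
posterior chest band; a skin shell defined by exact anisotropic Euclidean
distance to the exterior (thickness 2 mm default, optionally varying 1–3 mm
along the slice axis); dense blobs filling a target fraction of the
interior; bright fat (mean 200), dark skin and dense tissue (57 and 60),
near-zero background (2), and an intermediate chest band (90). Noise has a
thermal component everywhere (sigma 6) plus extra heterogeneity of the dark
tissues (sigma 5, total ≈ 7.8) so that the skin/dense gap of 3 stays below
half their spread — intensity alone cannot separate them, which is the
regime the method exists for — while both remain well above background, as
in real thresholded T2 data. Default geometry is a 128×128×40 grid at
1×1×2 mm with 25 mm breasts, sized so a full pipeline run takes seconds;
optional flags add inter-slice gaps (slices with missing skin), one-voxel
dark filaments and dense spurs, a nipple bulge, and a dense blob fused to
the skin at the nipple.

What the phantom does *not* model: MR physics (no sequence or k-space
simulation, no bias field, no partial-volume mixing beyond what smoothing
introduces), lesions or masses (excluded from the method's scope), and
anatomical variability of the chest wall. Passing tests therefore show the
algorithm implements its specification on geometry with the stated contrast
structure, not that it meets any clinical accuracy bar.

## Biomechanics

All three tissues use the neo-Hookean strain-energy form
`W = C1 * (I1bar - 3) + (1/d) * (J - 1)^2` with `C1 = mu0/2` and
`K0 = 2/d`; presets are fat 3 kPa, glandular 12 kPa, skin 50 kPa, with `d`
from the incompressible approximation `K0 = 1000 * mu0` when unspecified.
The committed error between plate reaction forces computed with real skin
and with a 1 mm 2D-membrane skin is `|F_real - F_mem| / F_real * 100`; the
formula choice is validated by reproducing, to one decimal, all seven rows
of the bundled compression table (`reaction_forces()`), whose breast
compression percentages are carried as metadata only. The finite-element
compression simulation itself (meshing, contact, gravity pre-load) is out
of scope; the package evaluates the material model and the error metric.

## Numerical choices and conventions

- Arrays are `(row, col, slice)` with spacing in mm per axis; the row index
  grows toward posterior. DICOM slices are ordered by position along the
  slice normal, never by filename; stored values are treated as unsigned
  (negatives after rescale are clamped to 0).
- Label codes are fixed — background 0, skin 1, fat 2, dense 3 — and written
  next to every label map as a JSON code table.
- Connectivities: 8 in-plane for components, 4 for the neighbour-count
  filter, 6 in 3D for background contact (26 available).
- mm→voxel conversions use the smaller in-plane spacing and ceiling
  rounding.
- The curvature-flow update is clamped to the input range (exact max
  principle); zero-gradient voxels receive a zero update.
- `split_breasts()` offers a per-slice frontier mode, but the default is one
  aggregated frontier ("from all slices"), which is far more noise-robust.
- Degenerate inputs fail loudly: constant volumes warn and pass through the
  threshold, clustering refuses fewer distinct values than clusters, label
  maps refuse to serialise the transient `MIXED` class.

## Problem sizes in the test suite

The suite generates everything it needs at run time: unit tests use
80×112×24 phantoms (about two seconds per pipeline run), the property
suites use the default 128×128×40 phantom, 50 random 16³ volumes for the
max principle, one 64³ noisy disk for the half-step integration check, and
200 random 1-D samples (n ≤ 12) for the clustering oracle. These sizes are
the package's own choice of a thorough-but-quick regression net; the
pipeline itself has no size assumptions and reads full 512×512×80 series.

## Known limitations

- The nipple region is a fixed anterior fraction of each breast's extent;
  no intensity-based nipple detection is attempted.
- The skin march operationalises the "dynamic search" as a depth-limited
  flood from the boundary through candidate voxels; ray- or normal-based
  marching would differ on strongly non-convex slices.
- Breasts are processed independently after a single global frontier; very
  asymmetric chest walls would benefit from the per-slice frontier mode.
- The 3D closure can add skin on slices that truly contain none (the price
  of guaranteeing a sealed surface), which is also the behaviour reported
  for the original method.
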