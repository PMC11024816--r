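---
title: "Whole-volume tract morphometry: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-volume tract morphometry: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractmorph)
```

## The problem and the model

Conventional tract analyses reduce a white-matter bundle's diffusion metrics
to one average, to 20-100 along-tract profile values, or to a voxel-thin
skeleton. All of these discard variation in the directions orthogonal to the
tract's core. `tractmorph` instead represents the *whole volume* of a tract
as a fixed-topology hexahedral mesh and compares subjects element by
element.

The pipeline has three stages:

1. **Mesh morphing (free-form deformation).** A template mesh of the tract
   (default: 16 x 16 x 80 = 20 480 hexahedral elements swept along a gently
   curved centerline) is embedded in a coarse regular "wrapper" lattice with
   a trilinear per-cell basis. Each mesh node has fixed *material
   coordinates* (cell index plus local coordinates) in that lattice. Fitting
   alternates (a) matching every surface node to its nearest point of the
   subject's tract surface cloud and (b) solving a regularised linear
   least-squares problem for the lattice control points,

   minimise over control points C:
   sum_s || W_s C - y_s ||^2 + lambda * mse(spacing) * || L (C - C0) ||^2,

   where `W_s` are the fixed trilinear weights of surface node `s`, `y_s`
   its matched cloud point, and `L` a graph Laplacian on the control grid
   acting on displacements. All nodes - internal ones included - then move
   through the same lattice, which is what preserves the relative positions
   of interior tissue and makes the deformed meshes comparable across
   subjects: every subject ends up with the same node and element count.
   Fit quality is the surface RMSE, the root mean square over surface nodes
   of the distance to the nearest cloud point.

2. **Metric embedding.** Each diffusion metric volume (FA, MD, AD, RD;
   NIfTI) is reduced to its masked voxel centres in world millimetres. Every
   element's centroid receives the value of the *nearest* masked voxel
   centre - pure nearest-neighbour lookup, no interpolation, ties broken by
   smallest voxel linear index. Elements whose nearest masked voxel is
   farther than a cap are flagged `unassigned` and excluded downstream.

3. **Cohort statistics.** Subjects x elements matrices (one per metric, or
   flattened node coordinates for shape) are centred and scaled per column,
   then analysed by PCA via SVD of the subjects x features matrix (the
   features x features covariance is never formed; with ~30 subjects and
   20 480 features that matters). Element-wise two-sample t-tests give t and
   p fields over the template; group mean and mean +/- 1 and +/- 2 SD
   fields visualise within-cohort variation patterns.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| template resolution `n_u, n_v, n_w` | 16, 16, 80 | elements | 20 480 elements total; the factorisation balances cross-section vs axial granularity for a tube-like tract and is configurable |
| lattice cells | 4 x 4 x 4 | cells | coarse enough for smooth anatomical warps, fine enough to track tract-scale shape |
| wrapper margin | 10% of largest extent | mm | keeps all nodes strictly interior with headroom for deformation |
| `smoothing_weight` lambda | 0.01 (x mean squared spacing) | - | makes the normal system well-posed when cloud coverage is uneven; small enough not to bias dense fits |
| `rmse_tol` | 1e-3 | mm | stop when surface RMSE stops improving at the micrometre scale |
| `max_outer_iters` | 30 | - | fits converge in 10-25 iterations in practice |
| correspondence | node -> nearest cloud point | - | clouds (segmentation surfaces) are denser than surface nodes; symmetric mode available |
| `max_dist` cap | 2 x max voxel spacing | mm | prevents background leakage when the morphed mesh slightly overhangs the mask |
| sampling site | element centroid | - | one value per element = the 20 480-long feature vector; per-node sampling with corner averaging available behind `at = "node"` |
| t-test flavour | pooled Student's | - | Welch and paired variants via `test_type` |
| multiple testing | off | - | the element maps are uncorrected p-value fields; BH-FDR available via `fdr = TRUE` |

PCA is run per metric (and on shape alone), with an optional combined mode
concatenating all four standardized metric blocks. The loading sign is fixed
(largest-magnitude entry positive) so runs are machine-comparable.

## What the synthetic generator emulates - and what it does not

`generate_cohort()` produces, per subject: a warped copy of the template
(control points of a 2 x 2 x 2 wrapper lattice perturbed by seeded Gaussian
displacements, SD = `shape_warp_scale`, default 2 mm), a dense surface
cloud sampled on the warped boundary (>= 10x the surface node count), and
four voxelized metric volumes (default 2 mm isotropic). Masked voxels get

    baseline(material coords) + subject intercept + group effect + noise,

with FA falling 0.65 -> 0.35 from core to rim, MD/AD/RD constant at
0.80/1.20/0.60 x 10^-3 mm^2/s, and the case-group effect confined to an
axial interval of material coordinates. Default cohort sizes are 20 cases
and 12 controls, the scale of the study this package emulates.

Deliberate choices, and their consequences for what a green test means:

* The 2 x 2 x 2 generator lattice shares its box with the default 4 x 4 x 4
  fitting lattice, so every generated warp is exactly representable by the
  fitting basis. The fitted RMSE therefore measures correspondence and
  sampling error, not basis mismatch. Real anatomy is not in the fitting
  basis's span; real-data RMSE has an extra approximation term the
  synthetic benchmark does not probe.
* Surface clouds are noise-free samples of a smooth warp. Segmentation
  jitter, topology errors and missing patches are not emulated.
* Metric volumes have stationary Gaussian noise and a box-shaped effect
  region. Real DTI noise is spatially correlated and Rician-flavoured.
* A voxel's value enters every element whose centroid maps to it, so
  neighbouring elements are correlated by construction - exactly as in the
  real pipeline where elements are finer than voxels.

## Numerical choices

* **Nearest-neighbour queries** use a uniform-grid index whose distance
  arithmetic is bit-identical to the brute-force scan, so results (including
  the smallest-index tie-break) are exactly reproducible and are
  property-tested against a brute-force oracle.
* **Rasterization** decides voxel-in-element by Newton inversion of the
  trilinear map (25 iterations, 1e-13 step tolerance); a voxel claimed by
  several elements keeps the smallest element index.
* **Standardization** drops columns with SD < 1e-12 and records them;
  whether to drop or pseudo-count zero-variance features is a genuinely open
  design point, and dropping is this package's documented rule.
* **Zero-variance t-tests** (both groups constant at an element) are
  undefined; t is reported NA, p is set to 1 and the element flagged.
* **Degenerate shape PCA** (identical geometry in all subjects) is reported
  explicitly (`degenerate = TRUE`, zero scores) rather than erroring.
* The **fitting objective is provably non-increasing** (nearest-point
  matching can only lower it; the inner solve is exact), which the tests
  assert on every fit.
* The objective's Laplacian penalty is scaled by the mean squared lattice
  spacing so `smoothing_weight` keeps one meaning across template sizes.

## Open design points resolved here

* The 20 480-element count has no stated factorisation; 16 x 16 x 80 is this
  package's default, not a fact about the original template.
* The template here is parametric (swept elliptical cross-sections with a
  squircle corner map, which keeps all element Jacobians positive) rather
  than derived from a subject segmentation, so the pipeline is
  self-contained.
* Lattice order (trilinear), resolution, regularisation and convergence
  thresholds are documented defaults; the upstream method's were not
  recoverable.
* The cluster-separation score is the area under the ROC of PC1 as a ranker
  of group membership. Because PCA signs are arbitrary with respect to
  groups, the separation score is orientation-free, `max(a, 1 - a)`; the raw
  oriented AUC (0.5 under label permutation) is also reported.

## Validation design

The test suite validates each stage against independent oracles: brute-force
face counting for surface extraction, affine reproduction for the trilinear
lattice (linear precision), tetrahedral-decomposition containment for
rasterization, an all-pairs scan for nearest-neighbour assignment,
`stats::t.test` for the vectorised t fields, and nibabel for the NIfTI
reader/writer. End-to-end, seeded synthetic cohorts with a known effect
region are pushed through simulate -> fit -> embed -> test/PCA and checked
for calibration (null rejection rate ~5%), recovery (sensitivity inside the
truth region, specificity outside, PC1 separation) and the shape/metric
dissociation: when only metrics differ between groups, metric PCA separates
the cohorts while shape PCA stays at chance. Cohort-level checks run on a
scaled 8 x 8 x 32 template to stay inside a desktop CPU budget; the
template-dimension and fitting-accuracy checks use the full 20 480-element
mesh. Because a single chance-level AUC draw at n = 10 + 10 has an SD of
about 0.13, the shape-PCA band [0.3, 0.7] is asserted on the median across
the ten seeded cohorts.

## Known limitations

* Fitting quality depends on the cloud being denser than the surface nodes;
  the reported RMSE has a floor set by cloud spacing.
* Nearest-point correspondence is local: initial misalignments beyond
  roughly a cell size can settle into a wrong basin. Inputs are assumed
  affinely pre-aligned (same scanner space), as in the intended workflow.
* No image registration, tensor fitting or tractography is performed; the
  package starts from segmented tract surfaces and scalar metric volumes.
* Element-wise p-value fields are uncorrected by default, matching the
  visual-map use case; switch on BH-FDR for inferential claims.
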