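---
title: "Methods: template patching, sliding semilandmarks, and their pitfalls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template patching, sliding semilandmarks, and their pitfalls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiland)
```

# The measurement model

`semiland` quantifies 3D shape with three classes of points on a triangle
mesh, recorded per specimen in a `LandmarkConfig`:

* **landmarks** — discrete points at biologically homologous positions.
  They never move after digitization.
* **curve points (sliding semilandmarks)** — points constrained to an
  anatomical outline between two landmarks. Their position *along* the curve
  carries no homology, so they are allowed to slide along the local curve
  tangent during optimization.
* **surface points (surface semilandmarks)** — points on a bounded surface
  region. They slide within the local tangent plane of the mesh.

Two operations make high-density configurations practical at scale:

1. **Patching** transfers a template's surface points onto each specimen
   semi-automatically, so only landmarks and curves are digitized by hand.
2. **Sliding** removes the arbitrary along-curve / within-surface placement
   by minimizing a deformation criterion against a reference shape.

After patching and sliding, configurations are jointly superimposed with
generalized Procrustes analysis (`gpa()`), which removes position, scale
(centroid size), and rotation, and ordinated by PCA.

# Thin-plate splines and bending energy

The deformation engine is the 3D thin-plate spline (`fitTPS()`), kernel
$U(r) = r$. For source points $X$ (k x 3) the spline solves

$$L \, W = Y, \qquad
L = \begin{pmatrix} K + \lambda I & Q \\ Q^\top & 0 \end{pmatrix},
\qquad Q = (\mathbf{1} \mid X),$$

with $K_{ij} = -\,\lVert x_i - x_j \rVert$. The sign is the one convention
under which the **bending-energy matrix**
$B$ (the upper-left k x k block of $L^{-1}$ restricted to the non-affine
subspace) is symmetric positive semidefinite and annihilates affine
configurations, i.e. $B\,(\mathbf{1} \mid X) = 0$; this was verified
numerically before the implementation was fixed. Bending energy of a map
$X \to Y$ is $\mathrm{tr}(Y^\top B\, Y)$: zero exactly for affine maps,
growing with localized deformation. With $\lambda = 0$ the spline
interpolates its targets exactly; $\lambda > 0$ trades interpolation for
smoothness (useful with noisy or duplicated sources). Degenerate sources
(k < 5 or coplanar configurations, for which the 3D kernel system is
singular) fall back to the affine least-squares map with zero bending
energy.

# Patching: warp, inflate, deflate

`buildAtlas()` binds a template mesh to its full configuration. Templates
should be *smooth* and *dense*: the template mesh itself is TPS-warped to
every specimen, and coarse templates (below about 10,000 faces; ~18,000 is a
proven default) deform poorly — the constructor warns.

`placePatch()` then, per specimen:

1. fits the TPS from the atlas fixed points (landmarks + curve points,
   curves resampled to the atlas budget) to the specimen's fixed points;
2. warps atlas surface points and the atlas mesh (the "intermediate model");
3. displaces each warped point by `inflate` along the warped template
   normal;
4. deflates: casts a ray back along the negative normal and takes the first
   specimen contact, falling back to the positive direction and finally to
   the globally nearest surface point;
5. optionally (`relax_to_atlas`) relaxes placements toward the atlas by
   tangent-plane sliding.

**Inflation** exists because step 4 can capture points on *internal*
structures (endocranial walls, trabeculae): pushing points outward first
makes the back-cast hit the outer surface. The trade-off is geometric:
convex regions tolerate large inflation, concave regions (fossae, vaults'
inner curvature) can see inflated points jump past a neighbouring external
surface. Hence inflation is a per-region decision (`piecemealPatch()`
accepts `inflate_per_region`), `inflate_mode = "relative"` scales by
specimen centroid size, and diagnostics matter more than defaults: each
`PatchResult` reports per-point distance-to-surface, agreement between the
hit-face normal and the template normal (negative values indicate placement
on an internal or reversed surface — "face inversion"), the projection
method used, and an off-region flag for placements that jumped much farther
than the local point spacing.

Failure is a *value*, not an exception: specimens whose fixed points float
off the mesh (the leading practical cause, typically a unit or export
mismatch) return `failed = TRUE` with a reason, so batch runs complete and
report. Patching small regions in isolation can invert faces; the remedy
implemented in `piecemealPatch(anchor_regions = )` is to include a
neighbouring region's fixed points as TPS anchors without patching that
region.

## Variably present structures

Two devices keep specimens with and without a structure in one analysis:

* **Negligible region** (`makeNegligibleRegion()`): an absent region is
  represented by n replicated coordinates at an anchor position — after
  joint alignment the region has near-zero size yet keeps configurations
  commensurate.
* **Negligibly sized hole** (`makeNegligibleHole()`): specimens lacking a
  fossa/foramen receive a minute fenced-off area (diameter of roughly one
  surface-point spacing) using the *same* fence labels as the real hole, so
  all specimens share one atlas. Fence labels are dropped
  (`dropPoints()`) before the joint alignment because they are not
  comparable across the two preparations. `runPyramidExperiment()`
  demonstrates the full workflow on synthetic pyramids and shows that the
  with/without-hole preparations of the same geometry stay mutually nearest
  in shape space.

# Sliding

`slideSemilandmarks()` iterates: build a reference (the evolving sample
mean, or a fixed reference), express it in each specimen's space, solve for
tangent-restricted displacements minimizing the criterion, damp by
`stepsize`, then re-project curve points onto their digitized polylines and
surface points onto the mesh.

* **Criterion**: `bending_energy` (default) minimizes the TPS bending energy
  of reference-to-specimen; `procrustes_distance` projects the residual to
  the reference onto the tangent structures (cheaper, metrically motivated,
  but known to over-contract points toward each other in some datasets).
* **Tangent structures** (`tangentStructures()`): one unit tangent per curve
  point from its neighbouring polyline points; an orthonormal tangent-plane
  basis per surface point from the supporting mesh face.
* **Stepsize** damps each update; the default 0.1 trades speed for the
  stability needed on dense configurations, where full steps (stepsize 1)
  can overshoot and crumple regions of high curvature before re-projection.
  `stepsize = 0` disables sliding (useful as a control), `1` takes the full
  GLS step.

At stepsize 1, before re-projection, the criterion is non-increasing across
outer iterations — this is asserted in the test suite, as is exact recovery
of a single point artificially displaced along a straight curve.

**Piecemeal sliding**: sliding group subsets separately (against their own
means) and pooling afterwards agrees closely with sliding everything
together when group structure is real; the test suite quantifies this with
random-skewers covariance correspondence and pairwise-distance regression
on a seeded two-group dataset.

# One-sided digitization and mirroring

Digitizing one side of a bilaterally symmetric structure and aligning
one-sided data exaggerates variance at the midline: with many bilateral
points and few midline points, the rigid Procrustes fit is dominated by the
lateral mass, and genuine midline variation is expressed almost entirely at
the midline points. `mirrorFill()` reflects the digitized side across the
least-squares midline plane to complete the configuration;
`midlineVarianceFraction()` quantifies the artifact, and
`bilateralVariant()` builds the four canonical designs (one-sided, plus
digitized contralateral landmarks, plus mirrored curves, fully mirrored) for
comparison. The packaged bilateral generator reproduces the inflation of
the one-sided midline fraction in essentially every seeded replicate.
Mirrored points are imputations: for analyses of asymmetry they must be
dropped again after alignment.

# Sampling sufficiency and dataset comparison

* `samplingCurve()` subsamples the point set at every size k, re-aligns, and
  measures the Procrustean correlation between subsample and full-data
  specimen scores; a plateau indicates sampling sufficiency, and the
  smallest k reaching fit 0.90/0.95/0.99 is reported. The fit at k = n is
  exactly 1 by construction.
* `fitBetweenDatasets()` gives the same Procrustean fit between two
  alignments of the same specimens, with a permutation test (the statistic
  matches `vegan::protest`'s correlation, which the tests verify).
* `randomSkewers()` compares covariance structure by applying common random
  unit selection vectors to both matrices and averaging response cosines;
  identical (or proportional) matrices score exactly 1.

# Curve budgets

`resampleCurve()` enforces even spacing along each digitized polyline
(endpoints pinned), and `allocateCurvePoints()` distributes a total budget
over curves proportionally to length with largest-remainder rounding,
clipped to [5, 30] per curve by default — oversampled curves impede the
patching warp, and ~20–30 points cover even long outlines. The `spacing`
mode instead matches curve-point density to the surface-point spacing.

# Synthetic fixtures

All generators are deterministic under a seed and record their parameters in
a manifest: `makePyramid()` (watertight pyramids, optional spherical-cap
fossa, fence curves, surface grids), `makeHemisphereTemplate()` (closed
hemispherical template at a target face count), `makeBilateralDataset()`
(symmetric base shape + symmetric modes + digitizing noise + optional
asymmetry), `makeTwoGroupDataset()` (30 + 10 style grouped pyramids with
jittered, directly digitized surface grids), and
`makePyramidExperiment()`/`runPyramidExperiment()` (the 16-configuration
negligible-hole experiment).

# Design choices and limitations

* **Indexing**: faces are 1-based inside the package, following R
  convention; 0-based indices appear only at the PLY/STL file boundary.
  (A 0-based internal convention was considered and rejected: every R-side
  subscript would need translation, a standing invitation for off-by-one
  defects.)
* **Geodesics are not computed.** The off-region diagnostic uses a
  Euclidean jump proxy; true geodesic tests would need a mesh distance
  library out of scope here.
* **Sliding solves a dense GLS system** per iteration; configurations with
  several thousand sliding points will be slow in this reference
  implementation.
* **Mesh I/O** covers ascii/binary PLY (both endiannesses) and ascii/binary
  STL with vertex welding; other formats should be converted externally
  (`semiland-cli.R convert-mesh`).
* **The mirroring artifact depends on the design.** With *few* bilateral
  points relative to midline points, one-sided rigid fits can instead absorb
  genuine midline motion and deflate the midline fraction; the packaged
  generator defaults (48 pairs vs 5 midline points) reflect the
  high-density semilandmark regime in which the documented inflation holds.

# Command-line interface

`system.file("scripts", "semiland-cli.R", package = "semiland")` is a thin
Rscript front end (`convert-mesh`, `resample-curves`, `patch`, `slide`,
`align`, `pca`, `mirror`, `sampling-curve`, `skewers`, `synth`) around the
functions above. Runs are configured by a JSON file, flags override file
values, and every run writes a `manifest.json` sufficient to re-run it.
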