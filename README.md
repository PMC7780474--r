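# semiland

Sliding and surface semilandmarks for 3D geometric morphometrics: triangle-mesh
handling, thin-plate-spline (TPS) warping, template-based patching of surface
points, semilandmark sliding, Procrustes alignment, and the evaluation tools
needed to check that those choices did not distort the downstream analysis.

## Background

Landmark-based morphometrics compares shapes through point configurations in
coordinate correspondence. Fixed anatomical landmarks are easy to place but
sparse; curves and surfaces between them carry most of the shape signal and are
captured with *semilandmarks* — points whose exact position along a curve or
across a surface is not homologous and is therefore allowed to slide during
alignment. This package implements the full pipeline:

- **Meshes** (`TriMesh`): PLY and STL reading/writing (ASCII and binary),
  nearest-point projection and ray casting against the surface (compiled
  kernels, with brute-force R oracles in the test suite).
- **Configurations** (`LandmarkConfig`): typed points (landmark / curve /
  surface), regions, bilateral sides, canonical ordering, CSV interchange.
- **TPS** (`fitTPS`, `warpPoints`, `bendingEnergy`): 3D thin-plate splines
  with kernel `U(r) = -r` so the bending-energy form is positive semidefinite;
  exact interpolation at `lambda = 0`, smoothing fits for `lambda > 0`.
- **Patching** (`buildAtlas`, `placePatch`, `piecemealPatch`): project a
  template's surface-point grid onto each specimen by TPS warp, inflation
  along normals, and ray-cast deflation back onto the mesh, with per-point
  diagnostics and failure-as-value (`PatchResult`).
- **Sliding** (`slideSemilandmarks`): iterative GLS sliding of curve and
  surface semilandmarks restricted to their tangent structures, minimizing
  bending energy (or Procrustes distance) against a reference, with a
  configurable stepsize (default 0.1) and per-iteration trace.
- **Negligible features** (`makeNegligibleRegion`, `makeNegligibleHole`):
  replicated points and minuscule fence curves that let structures with and
  without an anatomical feature (e.g. a fossa or foramen) be analyzed in one
  coordinate system at negligible cost to the common shape space.
- **Evaluation** (`samplingCurve`, `fitBetweenDatasets`, `randomSkewers`,
  `midlineVarianceFraction`): sampling curves for landmark budgets, PROTEST
  fits between datasets, covariance-matrix comparison by random skewers, and
  the midline-inflation diagnostic for one-side-only digitizing designs.
- **Synthetic fixtures** (`makePyramid`, `makeHemisphereTemplate`,
  `makeBilateralDataset`, `makeTwoGroupDataset`, `makePyramidExperiment`):
  deterministic mesh + configuration generators used throughout the tests.

## Worked example

A pyramid template with a 9 x 10 surface-point grid is patched onto a
differently proportioned specimen, then the full 16-configuration
negligible-hole experiment is run: ten pyramids of varying proportions, four
with a circular fossa; the six fossa-free specimens are patched both with a
negligible-hole fence and without, and all 16 configurations are aligned
together.

```r
library(semiland)

tpl <- makePyramid(surface_grid = c(9L, 10L), mesh_resolution = 12000L,
                   specimen_id = "template")
atlas <- buildAtlas(tpl$mesh, tpl$config, tpl$curves)
atlas
#> Atlas: template with 12150 faces; 37 fixed points, 90 surface points, 8 curves, 1 regions

spec <- makePyramid(base_depth = 1.3, height = 1.6, corner_skew = 0.1,
                    mesh_resolution = 2400L, specimen_id = "spec01")
fixed <- dropPoints(spec$config, function(p) p$class == "surface")
res <- placePatch(atlas, spec$mesh, fixed, inflate = 0.02)
res
#> PatchResult: 90 surface points placed; max distance-to-surface 1.24e-16; 0 internal-side, 0 off-region

head(res@diagnostics, 3)
#>             label     distance normalAgreement  method offRegion
#> surf_001 surf_001 0.000000e+00               1 ray_neg     FALSE
#> surf_002 surf_002 2.775558e-17               1 ray_neg     FALSE
#> surf_003 surf_003 2.775558e-17               1 ray_neg     FALSE

ex <- runPyramidExperiment(seed = 1)
ex$alignment
#> AlignmentResult: 16 specimens x 127 points; PC1-4 cumulative variance 98.7%
round(ex$cumvar4, 1)
#> [1] 98.7
```

Four principal components carry essentially all variance because the ten
pyramids differ in exactly three proportion parameters plus the fossa
presence; the negligible-hole fence adds no measurable variance of its own,
and each specimen patched with and without the fence lands at the same point
of shape space (see `tests/testthat/test-acceptance.R`).

## Command-line interface

`inst/scripts/semiland-cli.R` exposes the pipeline as subcommands
(`convert-mesh`, `resample-curves`, `patch`, `slide`, `align`, `pca`,
`mirror`, `sampling-curve`, `skewers`, `synth`), configured by JSON files with
flag overrides; every run writes a `manifest.json` that reproduces it.

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","semiland-cli.R",package="semiland"))')" \
  synth bilateral --seed 3 -o run1
Rscript .../semiland-cli.R pca --configs run1/configurations.csv -o pca1
```

## Reproduction

`scripts/acceptance.R` re-runs the headline experiment against the installed
package and writes the PC1–4 cumulative-variance target as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
# {"t1": {"value": 98.7…, "n": 16}}
```

The value is stochastic in the seed (the pyramid proportions are drawn from
seeded uniforms) and lands in the mid-to-high 90s across seeds.
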