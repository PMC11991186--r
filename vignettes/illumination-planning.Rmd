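---
title: "Optical-illumination planning of rigid-needle biopsy trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical-illumination planning of rigid-needle biopsy trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(illumipath)
```

## The model

Planning a percutaneous biopsy with a rigid needle means choosing a skin
entry point such that the straight segment from the entry to the target
(a lung nodule, say) is feasible and clinically preferred. illumipath
reformulates this search as a light-transport problem: a virtual
isotropic point source sits at the target `T`, every direction on the
sphere of radius `R` (the needle length) is a candidate trajectory, and
the "brightness" that survives along a ray encodes how acceptable that
trajectory is.

Three mechanisms encode the constraints:

* **Occlusion (hard constraints).** High-risk structures — bones, the
  heart, airways, non-target lung lobes — are opaque. A ray touching an
  opaque voxel carries the binary indicator `Iobs = 0` and is excluded
  outright. Obstacles are first dilated by a Euclidean ball of radius
  `obstacle_margin_mm` (default 2 mm), which converts the
  minimum-clearance rule into a hard constraint: any surviving ray clears
  every original obstacle voxel by at least the margin.

* **Beer–Lambert absorption (soft constraints on depth and vessels).**
  Passable tissue absorbs light: absorbance accumulates as
  `A = sum_i k_i * l_i` over the per-voxel chord lengths `l_i`, and the
  transmitted fraction is `10^(-A)`. Soft tissue carries `k = 0.02` per
  mm, so longer paths are dimmer (depth regulation); pulmonary vessels
  carry `k = 0.1` per mm, so vessel-rich corridors are penalised in
  proportion to the vessel thickness traversed, without any explicit
  vessel geometry processing. The two classes are accumulated
  separately into `Atra` (tissue) and `Avas` (vessels).

* **Lambertian reflection (insertion angle).** The skin is treated as a
  diffuse reflector: `Aref = max(0, cos(theta))`, with `theta` the angle
  between the ray and the outward skin normal. Perpendicular insertion
  gives 1; grazing insertion gives 0.

The per-direction score is the composed intensity

```
I = Iobs * Atra^alpha * Aref^beta * Avas^gamma
```

with non-negative exponents expressing the clinician's relative weighting
of depth, angle, and vessel risk. `0^0` is defined as 1, so a zero
exponent disables its term. All three attenuation terms live in `[0, 1]`
by construction — an absorbance of 0 transmits 1 (no penalty) — which is
the normalisation adopted here. The exponents default to `alpha = beta =
gamma = 1` since no canonical values exist; they are configuration
inputs.

A direction must also *reach* the skin: the candidate screen removes
directions whose ray never crosses the skin within `R`, whose crossing
falls outside the imaged volume, or whose ray re-enters labelled tissue
after leaving the skin (a multi-crossing geometry such as an arm fold —
rejected conservatively, since a needle cannot pass through air between
two skin patches). This screen deliberately ignores opacity, so the
planner can distinguish "the needle cannot reach the skin" from "every
reachable corridor is occluded" when reporting failures.

## From sphere to recommendation

The shell map is sampled on a latitude–longitude grid (default 1°,
configurable; the corpus and test problems use 2°) and projected to a 2-D
raster with the sinusoidal equal-area projection `x = lambda * cos(phi)`,
`y = phi`, centred on the anterior (ventral) direction, which is taken as
`-y` in the patient frame. Equal-area matters: region sizes in the image
are proportional to solid angles on the sphere, so "large bright region"
means the same thing in 2-D as in 3-D. The three quantities map to RGB
channels: R = `Avas`, G = `Atra`, B = `Iobs * Aref` (the binary indicator
is folded into the blue channel, so `B > 0` marks feasible directions).

Candidate safe regions are 8-connected components of the thresholded
raster (defaults: `B > 0`, `G >= 0.05`, `R >= 0` — vessels are penalised
through intensity rather than excluded) with components smaller than
about 25 square degrees dropped. Each region is summarised by a fixed,
versioned 50-entry feature vector (shape descriptors, normalised central
moments, Hu invariants, per-channel intensity statistics, green-weighted
centroid, distance to the image centre; see `region_feature_names()`).

Region preference is learned from annotations: a 100-tree random forest
with maximum depth 10 and balanced class weights (ranger), trained on a
grouped 7:1:2 image-level split — all regions of one image stay in one
subset, so no leakage — after SMOTE-style minority oversampling of the
training rows (synthetic samples interpolate between nearest minority
neighbours; parity with the majority class). Gradient boosting (xgboost)
is available behind the same interface. At inference the
highest-probability region wins (ties: larger area, then centroid nearest
the image centre); the chosen region is eroded with a 3x3 structuring
element until a single pixel survives, and that pixel's direction is
mapped back through the stored skin crossing to the 3-D entry point.

Reported path metrics: depth (mm, entry to target), the angle between the
needle and the skin *surface* in degrees (90° = perpendicular; this is
`90° - theta`, where the Lambertian model uses `theta` from the normal —
the two conventions are easy to confuse), and the minimum distance to any
un-dilated obstacle, sampled every half voxel along the path against the
exact Euclidean distance transform.

## The synthetic phantom and what it does (not) show

Real evaluations of this pipeline require annotated CT with expert
segmentations, which cannot ship with a package. The `phantom` module
generates seeded, parametric thorax-like label volumes instead: a body
ellipsoid with a one-voxel skin shell (exactly the body voxels
face-adjacent to background), two lung ellipsoids split into 2–5 lobe
compartments, branching vessel trees with graded radii (3.5/2.2/1.2 mm),
rib arcs with an 80° ventral gap, an opaque heart blob and airway tube,
and a 6 mm nodule strictly inside the target lobe. Default grid 64³ at
2 mm spacing; generation is bit-reproducible given the seed, and each
phantom is verified by a brute-force ray sweep to contain at least one
obstacle-free corridor (otherwise the geometry is perturbed
deterministically and regenerated).

The "surgeon" annotations on the synthetic corpus come from a fixed,
documented rule — the preferred region maximises area × mean green
intensity, ties toward the image centre — with optional label-flip noise.
This makes classifier recovery *measurable*: a pipeline bug that corrupts
features or leaks groups shows up as a drop in held-out AUC. What passing
does **not** show is anything about real surgeon preference: the rule is
a two-feature function, far simpler than clinical judgement, and phantom
anatomy lacks CT noise, segmentation errors, respiratory motion and the
true vessel topology. Results on the phantom corpus validate the
machinery, not the clinical model.

```{r, eval = FALSE}
vol <- generate_phantom(phantom_spec(seed = 3))
plan <- plan_path(vol, cfg = phantom_tissue_config(), needle_mm = 153,
                  resolution_deg = 2)
plan
plot(plan)
```

## Numerical choices

* **Exact ray traversal.** Rays are marched with the Amanatides–Woo
  voxel traversal: each traversed voxel contributes its exact chord
  length, so the per-class absorbance is the exact line integral of the
  piecewise-constant absorption field — there is no sampling-step error
  to tune, and a dense 0.1-voxel midpoint oracle agrees to a fraction of
  a percent. A fixed-step nearest-voxel sampling mode is kept behind the
  `step` argument of `cast_ray()` as a reference. Early ray termination
  (stop at the first opaque voxel) and empty-space skipping (clip the
  march to the bounding box of absorbing/opaque/skin voxels, with the
  image-exit time computed analytically) are pure optimisations: every
  output is defined "up to the stopping point", so toggling them changes
  nothing, which the test suite checks to 1e-12.

* **Skin normals.** The outward normal is the gradient of a
  Gaussian-smoothed body mask, evaluated with a derivative-of-Gaussian
  kernel centred exactly on the query point. The smoothing sigma
  defaults to 2 voxels: a discretised smooth surface develops flat
  axis-aligned facets of radius about `sqrt(2 r)` voxels, and a 1-voxel
  kernel leaves normal errors above 10° there, while sigma = 2 stays
  within ~3.5° of the analytic normal on sphere benchmarks (the package
  targets 5°). Degenerate zero-gradient points fall back to the ray
  direction, with a message.

* **Distance transform and dilation.** Obstacle distances use the exact
  Euclidean distance transform (Felzenszwalb–Huttenlocher, per-axis
  spacing aware). Dilation by `margin_mm` is implemented as thresholding
  that distance at the margin, i.e. an exact Euclidean ball; the stored
  distance field stays relative to the *original* obstacles so the
  clearance guarantee is auditable after dilation.

* **Resampling.** Labels are resampled to isotropic resolution at the
  smallest input spacing with nearest-neighbour lookup (the only
  label-safe interpolant); the world extent is preserved to within one
  output voxel per face.

* **Degenerate inputs.** A volume with no skin label is rejected; a
  target encased in bone yields a structured `full_occlusion` failure; a
  needle too short for any skin yields `no_skin_reach`; thresholds that
  leave no region yield `no_region`. `plan_path()` returns these as data,
  not errors, so batch studies can tabulate them.

* **Ties.** Erosion returns the survivor closest to the centroid of the
  last non-empty set (ties: smallest row, then column). Region selection
  ties break by area, then centroid-to-centre distance. All tie-breaks
  are deterministic and tested.

## Problem sizes and reproducibility

The bundled tests and the acceptance script run entirely on synthetic
data at desk scale: 48³–64³ phantoms at 2 mm spacing, 2° shell
resolution for corpus work (1° for geometry checks), a 200-image corpus
split 150/50 for recommender evaluation, a 20-seed label-permutation
null, and 20 fresh phantoms for end-to-end path metrics with the fixed
153 mm needle. These sizes were chosen so the full study reruns in
minutes while leaving every moving part exercised; every random draw is
controlled by an explicit seed argument.

## Known limitations

* The planner assumes axis-aligned, positive-direction volumes; oblique
  CT orientations must be resampled upstream.
* Regions that straddle the ±180° meridian of the projection are split
  into two components; corridors near the posterior midline can
  therefore be fragmented. The anterior projection centre makes this
  rare for the intended (ventral-access) use.
* The Lambertian term uses the smoothed-mask normal; on very coarse
  grids (> 3 mm) the angle estimate degrades with the mask resolution.
* No multi-needle planning, ablation coverage, respiratory motion, or
  learning of segmentation thresholds from data.
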