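---
title: "Virtual ureteroscopy from CT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual ureteroscopy from CT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`uroscope` turns a delayed-phase CT volume of a kidney into simulated
endoscopic views of the renal collecting system. This vignette documents the
science in each stage, the tunable parameters, the numerical decisions, and
what the synthetic phantoms do and do not establish about clinical data.

## The problem

Ureteroscopy navigates the renal collecting system — the urine-filled cavity
formed by the renal pelvis and its branching calyces — with a camera-bearing
scope. A surgeon plans this navigation from 2D axial CT slices. The
pipeline here builds the bridge: segment the collecting system from CT,
reduce it to a centerline graph, fly a virtual camera along that graph, and
render endoscopy-like interior views whose realism can then be improved by
unpaired style transfer and measured with image-distribution distances.

## Preprocessing (`volumes_io`)

CT intensities are clipped to the `[-256, 512]` HU window and mapped
affinely to `[0, 1]`; this window spans soft tissue through pooled contrast
while discarding air and metal extremes. Volumes can be resampled to a fixed
grid (e.g. 256 cubed) before inference. Decisions made where the procedure
was open:

* **Interpolation.** Trilinear for intensities, nearest-neighbour for label
  maps (labels must never blend). Both routes share one cell-centered
  convention — voxel `i` sits at `(i + 0.5) * spacing` — and resampling
  preserves the physical extent `shape * spacing` per axis exactly, so the
  output spacing is the input extent divided by the target shape.
* **Axis convention.** Arrays are indexed `(z, y, x)`; spacing and world
  coordinates are `(x, y, z)` in mm. Every documented API states this.
* **Out-of-window values** clamp rather than error: a metal implant maps to
  1, air to 0.

## Collecting-system extraction (`extraction`)

The collecting system is not segmented directly: it is small relative to the
scan, so a whole-kidney mask is produced first (by any voxel
predictor behind the `Predictor` interface) and the bright cavity is isolated
in post-processing:

1. dilate the kidney mask with a 5 x 9 x 9 box (z, y, x) so the cavity is
   fully covered even when the mask is tight — on thick-slice CT
   (about 5 mm slices vs about 0.8 mm in plane) this box is roughly isotropic
   in mm;
2. restrict the CT to the dilated mask;
3. three-class Otsu thresholding of the masked intensities only —
   background, parenchyma and contrast-filled cavity form three modes on
   delayed-phase CT;
4. keep the highest-intensity class.

Otsu is computed on a 256-bin histogram of the observed masked range by
exhaustive search over all threshold pairs, so the result is the global
optimum of the discretized criterion; ties resolve to the lexicographically
first pair. Computing the histogram over masked voxels only (not the whole
volume) is deliberate: the masking exists precisely to remove irrelevant
tissue from the intensity distribution. An optional largest-connected-
component filter is exposed (`largest_cc`) but off by default, since the
upstream procedure is silent on it.

Sliding-window inference fuses overlapping patch predictions (default
128 cubed patches, overlap 0.5) by an unweighted voxelwise mean, with the
final window snapped inside the volume rather than padded — padding would
fabricate intensities. Training-time augmentations (intensity shifts within
±0.026, 16 balanced crops, ±30° rotations with ±10% scaling, Gaussian
smoothing with sigma in [0.5, 1.5] voxels) are provided as seeded operators;
training a 3D network itself is out of scope here because the clinical
training data are private.

## Meshing (`meshing`)

The binary cavity mask is smoothed with a Gaussian of sigma 0.8 voxels
(reflective boundary, kernel truncated at 4 sigma and renormalized) and the
0.5 level set is extracted as a triangle mesh in physical mm.

The iso-surfacer decomposes each cell into **six tetrahedra** sharing the
main diagonal rather than using the classic 256-case cube table. The
tetrahedral cases have no ambiguous sign configurations, so the surface of
any field that does not touch the volume boundary is closed and 2-manifold
by construction — a property the downstream wave propagation relies on
(BFS on a surface with holes would leak). The cost is roughly twice as many
triangles; on a sphere fixture the surface area is accurate to well under
1%, and values exactly on the iso level are nudged by a relative 1e-7 so
every crossing is strict and no degenerate triangles arise.

## Wave-propagation skeletonization (`skeleton`)

A wave is propagated across the mesh edge graph from a seed vertex by
breadth-first search; the "step" of a vertex is its hop distance. Vertices
at the same quantized step (`floor(step / step_size)`) that are connected
through mesh edges form a **ring**; each ring contracts to its centroid, and
rings in adjacent step groups sharing a mesh edge are joined. Requiring
edge-connectivity within a step group is what separates branches: past a
bifurcation the wavefront splits into two rings, yielding one skeleton node
per branch.

Choices made where the method description was open:

* **Metric.** Unweighted edge hops, the plainest reading of counting
  "steps"; hop counts on a reasonably uniform triangulation approximate
  geodesic distance well and are integer-exact.
* **Ring repair.** Triangulation irregularity occasionally splits one
  wavefront into fragments — one or two stray vertices at a branch-tip cap,
  or a lone local-maximum vertex. Two same-group rings sharing a neighbour
  ring whose centroids lie within the sum of their RMS ring radii are
  re-joined, and any "ring" with fewer than three vertices (too few to bound
  a cross-section) is absorbed into the neighbouring ring it shares the most
  mesh edges with. This is part of ring construction, not branch pruning:
  no branch of three or more rings is ever removed.
* **Seeds.** Deterministic farthest-point sequence: the first seed is the
  vertex farthest from vertex 1, later seeds maximize the minimum distance
  to the chosen set. No randomness is involved; `rng_seed` is recorded for
  provenance.
* **Wave averaging.** With `wave_count = 2` (the default), the second wave
  starts from the opposite extreme and node positions are averaged after
  matching. Matching is nearest-neighbour in 3D position with a radius of
  twice the median skeleton segment length; matching on a 1D arc-length
  coordinate alone would be ambiguous between branches at equal depth.
  Unmatched nodes stay unaveraged. Topology always comes from the first
  wave, so `wave_count = 1` reduces exactly to plain contraction.
* **Defaults** `step_size = 5`, `wave_count = 2`: on 1 mm phantom meshes
  this yields one node per about 5 mm of tube, dense enough for camera
  placement in the pelvis without oversampling the calyces.

Skeleton quality is quantified by the mean distance from 5000 area-uniform
surface samples to the nearest point on any skeleton **segment** (not just
nodes). Measuring to segments rather than nodes is a deliberate deviation
risk worth naming: a node-only metric would penalize sparse skeletons purely
for quantization, conflating sparsity with misplacement.

The centeredness contract (all nodes within 0.1 radius of the axis) is
stated for symmetric cylinder triangulations, where ring centroids lie on
the axis exactly; on marching-tetrahedra meshes of voxelized tubes the hop
metric's anisotropy adds a wobble of a few tenths of the radius at the caps,
which the two-wave averaging reduces but does not remove.

## Camera paths and rendering (`camera_render`)

Poses are placed at fixed arc-length intervals along a depth-first traversal
of skeleton edges, starting at a degree-1 node (the entry point on tubular
anatomy). The view direction is the local tangent; the up vector is
parallel-transported along each chain (projected onto each new tangent
plane), which avoids the roll flips a fixed world-up would cause at branch
turns. The vertical field of view defaults to 60° and is configurable —
real ureteroscopes are wider, and style-transfer realism depends on this
choice, so it is surfaced prominently.

The renderer is a software ray caster over a median-split BVH with Phong
shading `I = ambient*C + diffuse*C*max(0, n.l) + specular*max(0, r.v)^e`,
solid textureless base color, black background, and three presets:

| preset | ambient | diffuse | specular | light | edges |
|---|---|---|---|---|---|
| `baseline` | 0 | 1.0 | 0 | global directional | on, contrasting palette |
| `customsurface` | 1.0 | 0.3 | 0 | global directional | on |
| `customlight` | 0 | 0.5 | 0.1 | headlight | off |

"Headlight" places the light 1 mm behind the camera along the negative view
direction — the smallest faithful reading of a light source just behind an
endoscope tip; the offset is configurable. Distance falloff is **off** by
default (scene lights of fixed intensity); an inverse-square mode with a
reference distance of 10 mm can be enabled, under which wall brightness
decreases monotonically with distance. Normals are flipped toward the
viewer so interior walls shade correctly.

## Distribution distances and the style contract (`metrics_style`)

Rendered and target image sets are compared with the Fréchet distance
between Gaussian fits (`fid`) and the unbiased subset-averaged squared MMD
under the cubic polynomial kernel `(x.y/d + 1)^3` (`kid`). Numerical
policies: covariances use `1/(n-1)`; the matrix square root goes through the
symmetric form `(Sa^{1/2} Sb Sa^{1/2})^{1/2}` by eigen-decomposition with
small negative eigenvalues (relative 1e-8) clamped and large ones treated as
errors; KID defaults to subset size 100 and 10 seeded subsets, reported with
every estimate. The feature extractor is pluggable; everything in this
package uses a seeded random-projection extractor so no pretrained network
is required, which means absolute FID/KID values are **not** comparable to
inception-based numbers — only within-extractor comparisons are meaningful,
and the package only ever claims the direction of such comparisons (the
headlight preset scores closer to the endoscopy-style domain than the
wireframe baseline).

The patchwise contrastive (InfoNCE) loss used by unpaired translation is
provided with log-sum-exp stabilization (`patch_nce_loss`, default
temperature 0.07), and `style_smoke_train` exercises the full contract —
generator vs discriminator plus patch correspondence — at desk scale: a
12-parameter per-pixel color transform against a 7-parameter logistic
discriminator on channel statistics, optimized by central-difference
gradient descent. This validates the objective wiring and nothing more; it
is not a stand-in for a convolutional translation model.

## Synthetic phantoms (`synthetic_data`)

A phantom emulates the geometry and contrast regime of delayed-phase CT: a
prolate pelvis ellipsoid (semi-axes 10 x 9 x 13 mm) with an entry tube
(radius 4 mm) and 2-12 calyx branches (radius 3-5 mm, length 18-30 mm),
wrapped in a parenchyma shell built by morphological closing plus dilation,
with intensities background -100 / parenchyma 80 / contrast 300 HU and
additive Gaussian noise of SD 20 HU. The intensities are plausible HU
magnitudes chosen once for three well-separated modes — they are not
measured clinical values — and all are configurable. Calyx directions sit
on a jittered Fibonacci spiral over the upper polar cap so that the pole is
covered by a calyx mouth and neighbouring calyces never merge into one
lumen; ground truth includes the three-class label map and the
branch-structured centerline.

What passing on phantoms does **not** show: phantoms have uniform tissue
classes with ideal mode separation, no partial-volume mixing, no anisotropic
slice profile, no streak or motion artifacts, and no anatomical variation
beyond branch topology. Extraction Dice near 1.0 on phantoms therefore
validates the post-processing logic (dilate, mask, threshold, select), not
clinical segmentation accuracy, which depends on a trained predictor and
real data that are outside this package's scope.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script run phantoms at 128 cubed with
1 mm spacing, meshes of roughly 25k vertices, 5000-point coverage samples,
renders at up to 255 x 255, FID closed-form checks at n = 10000, and a
60-step style smoke run — sizes chosen so the full suite exercises every
stage end to end on a single CPU in minutes while keeping Monte-Carlo
tolerances meaningful.

Degenerate inputs fail loudly by design: empty kidney masks, histograms with
fewer distinct values than classes, fields that never cross the iso level,
empty skeletons, zero-area render targets and branches exceeding the phantom
grid all raise descriptive errors rather than returning empty results.

## Known limitations

* Hop-count waves are triangulation-dependent; strongly anisotropic meshes
  would benefit from the optional geodesic edge weighting, which is not the
  default.
* Skeleton centeredness is only guaranteed for tubular geometry; the pelvis
  blob yields nodes that are inside but not equidistant from walls.
* The renderer has no fisheye/distortion model, no textures and no global
  illumination; it reproduces the three lighting presets, not a specific
  commercial viewer.
* FID/KID values from the random-projection extractor are internally
  consistent but not comparable to inception-based reports.
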