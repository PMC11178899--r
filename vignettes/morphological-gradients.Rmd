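---
title: "Morphological gradients: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological gradients: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphgrad)
```

## The model

A scoring function $f$ maps a triangle mesh $M$ to a class belief in
$[0,1]$; in the craniofacial setting $f(M) = P(\text{female})$. The
morphological gradient asks a directly interpretable question: if this
patch of surface were pushed outward (as a surgeon might), how would the
belief change? Formally, for a center vertex $p_0$ and displacement
$\delta$ (mm), every vertex $p$ moves along its unit normal $N(p)$:

$$T(p; p_0, \delta) = p + \delta\,\sigma(\lVert p - p_0\rVert)\,N(p),
\qquad \sigma(r; R) = \max\left\{0, \frac{R - r}{R}\right\},$$

and the gradient at $p_0$ is $\nabla f(p_0) = f(T(M)) - f(M)$. A positive
$\delta$ makes a bump, a negative one a dent; the linear falloff
$\sigma$ produces a smooth, surgically plausible cone of influence —
$\sigma(0) = 1$ at the center, reaching zero exactly at the range $R$.

Assumptions worth stating:

* **Normals are those of the undeformed mesh.** $T$ references $N(p)$ of
  the input; normals are not re-estimated mid-deformation. This keeps $T$
  linear in $\delta$ for a fixed geometry.
* **Dent maps are not negated bump maps.** $f$ is nonlinear, so the
  dent field is obtained by running with $-\delta$, never by flipping the
  sign of the bump field.
* **The scorer is a black box.** Only evaluations of $f$ are used — the
  method applies equally to a neural classifier or an analytic score, and
  needs no gradient access.

## Sparsification: the vertex point cover

Dense evaluation costs one scorer call per vertex. Assuming the gradient
varies smoothly over the surface, it is evaluated only on a vertex point
cover $C(M; \rho)$: vertices are visited in breadth-first order from
vertex 1 and greedily admitted when no current cover vertex lies within
graph distance $\rho$. The result is complete (every vertex within
$\rho$ of the cover) and separated (no two cover vertices within
$\rho$), and the scorer is called exactly $|C| + 1$ times per field.

Distances are shortest paths on the edge graph with Euclidean edge
lengths — a strictly better geodesic proxy than hop counting, to which it
reduces on uniform meshes; a hop-count mode is retained behind
`mode = "hop"` since the traversal cost is the same and some meshes are
near-uniform. Cover values are interpolated to all vertices by
inverse-graph-distance weighting over the 3 nearest cover points
(exponent 1): exact at cover vertices, bounded by the cover-value range,
and cheap. Ties anywhere are broken toward the lower vertex index, making
every result deterministic.

The distance inside $\sigma$ is Euclidean by default (the literal reading
of $\lVert p - p_0 \rVert$); a geodesic mode is provided because straight-
line distance can drag surfaces that are spatially close but anatomically
distant, such as the inner and outer skull table.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `delta` | +2 | mm | bump height; surgical-scale perturbation |
| `range_R` | 20 | mm | falloff radius; sets the feature scale probed |
| `rho` | `range_R / 2` | mm | cover radius; scorer-call budget vs. field fidelity |
| rotation limit | 10 | degrees | augmentation bound |
| shift limit | 5 | % of axis extent | augmentation bound |
| mirror probability | 0.5 | — | augmentation |

`delta` and `range_R` are deliberate package defaults at the scale of
craniofacial alterations; both trade spatial resolution against
signal-to-noise in the score difference. A `rho` below the minimum edge
length degenerates gracefully to dense per-vertex evaluation.

The rotation is parameterized axis-angle (uniform random axis, angle
uniform in $\pm$ limit) about the centroid: a single interpretable angle
bound, whereas composed per-axis Euler rotations can exceed their nominal
limit, and rotating about the centroid does not alias into a translation.
"Size" for the shift is the per-axis bounding-box extent, drawn
independently per axis. The mirror plane is sagittal (x through the
centroid), and mirroring also reverses face winding so outward normals
stay outward. All draws come from one RNG stream; a seed makes the
composite bit-reproducible, and seeding is local so the caller's RNG
state survives.

## Voxelization

The voxelizer converts a mesh into the dense binary volume a volumetric
CNN consumes: a cubical grid over the largest bounding-box extent,
centered, with occupancy decided by exact triangle/box separating-axis
tests (the inner loop is compiled C++). Conservative intersection-based
occupancy — rather than sampling voxel centers — guarantees the shell of
a closed mesh is watertight at any resolution, so `fill_solid()` (an
exterior flood fill) can produce solid bone-like masks. Voxels are
half-open per axis; a triangle lying exactly on a shared voxel face
belongs to the lower voxel, so nothing is counted twice. Both hollow
shells and solid fills are available since either may match a given
training convention.

## The synthetic population and its scorer

The generator emulates the statistical structure of skull sexual
dimorphism, not anatomy: a subdivided icosphere scaled to a head-like
ellipsoid (lateral : front : vertical = 0.8 : 1.0 : 0.9), with three
interpretable axes of variation —

* **size**: `base_radius`, males $\mathcal N(95, 4)$ mm vs females
  $\mathcal N(90, 4)$;
* **brow**: a raised-cosine bump of height `brow_amplitude` (males
  $\mathcal N(3,1)$, females $\mathcal N(1,1)$, clamped at 0) on the
  upper-front patch (compact support, half-width 0.5 rad);
* **jaw width**: lateral scaling of the lower region by
  `jaw_width_factor` (males $\mathcal N(1.06, 0.02)$, females
  $\mathcal N(1.00, 0.02)$), smoothly ramped on below the lower third;

plus i.i.d. radial Gaussian noise (default 0.5 mm). The population
parameters are invented but chosen so that the classes overlap the way
real dimorphic measurements do: size alone separates at AUC ≈ 0.8, all
features together at ≈ 0.9, and a large `sex_effect` approaches perfect
separation. Default problem sizes (642-vertex meshes, populations of
100, 10,000 augmentation draws) were chosen as the smallest at which the
class-overlap and coverage properties are comfortably measurable.

The analytic scorer measures the three features from the mesh itself —
mean radial excess over a least-squares ellipsoid inside the brow patch,
lower/upper lateral width ratio, mean centroid distance — after pose
normalization by PCA axes, with the in-plane axis orientation chosen as
the sign combination maximizing the brow excess (anchoring "upper front"
to the most brow-like region, as anatomy does). The features are
standardized against frozen calibration constants (Monte Carlo moments of
the default population), winsorized at $\pm 3$ so no single feature can
dominate far outside its calibration regime, and combined as
$P(\text{female}) = \mathrm{logit}^{-1}(-(1.5 z_b + z_j + z_s))$, the brow
weighted highest as the leading localized dimorphic trait. Mean centroid
distance (rather than an extremal radius) is used for size deliberately:
a max statistic would let any single bumped vertex dominate the gradient
field, corrupting the localization ground truth the scorer exists to
provide.

Because the scorer is analytic, gradient maps have a known answer: on a
noise-free masculine proxy the field must concentrate in the brow patch
with negative sign (pushing the brow outward lowers P(female)), which is
exactly what the acceptance tests assert (patch-mean |gradient| at least
3× the outside mean). What passing these tests does **not** show: that
the method localizes features of a *trained network* on *real* skulls —
real CT surfaces have internal structures, truncation artifacts and
registration variation that the proxies do not model. The tests validate
the machinery, not the anatomy.

## Evaluation protocol

Stratified k-fold: each class is shuffled (seeded) and dealt round-robin,
classes consecutively, so per-class fold counts and total fold sizes are
each within one of the ideal. AUC is computed as the Mann–Whitney
statistic via mid-ranks — identical to exhaustive pair enumeration with
ties credited half — and is the primary metric because score calibration
drifts make fixed-threshold accuracy unstable even when ranking is good
(`accuracy_at()` exists as a secondary metric). Per-fold AUCs are always
reported individually: with 20-sample test folds the spread is large and
a mean alone would be misleading.

## Numerical choices and degenerate inputs

* Vertex welding on STL read is exact (bitwise) by default — exporters
  duplicate vertices verbatim, and epsilon welding risks collapsing
  genuinely close anatomy; an epsilon mode exists.
* Degenerate (zero-area) faces contribute zero weight to vertex normals;
  vertices with no usable normal are flagged rather than guessed.
* Disconnected meshes (floating fragments from segmentation) are covered
  per component; interpolation never bleeds across components.
* The diverging heat-map's red channel is strictly increasing in the
  scalar, so sign ordering survives 8-bit color quantization; the raw
  scalar is additionally stored in the PLY so no information is lost.
* Scorer outputs outside $[0,1]$ are contract violations and raise an
  error rather than being clamped.

## Known limitations

Graph-geodesic distance overestimates true surface geodesics on coarse
meshes (paths are confined to edges); exact polyhedral geodesics are out
of scope. The mirrored-field symmetrization assumes approximate bilateral
symmetry and uses nearest-vertex correspondence, not registration. The
voxelizer is CPU-bound and intended for desk-scale volumes; its contract
(not its speed) matches GPU voxelizers. Automatic region-of-interest
detection (e.g. excluding internal skull surfaces) is not provided —
`region_mask` accepts one computed elsewhere.
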