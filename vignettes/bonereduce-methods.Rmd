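---
title: "Virtual fracture reduction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual fracture reduction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonereduce)
```

# The problem

Comminuted fractures — of the tibial plateau in particular — leave a base
bone and several displaced fragments. Preoperative planning benefits from a
*virtual reduction*: repositioning segmented fragment meshes into anatomical
alignment and merging them into one surface model that can be inspected or
3D-printed. `bonereduce` implements the three computational stages of such a
semi-automatic workflow:

1. **Surface classification** — label each vertex of a segmented fragment
   mesh as *intact* (dense cortical shell) or *fracture* (freshly exposed
   cancellous bone) from per-vertex CT intensities in Hounsfield units
   (HU), and group fracture vertices into connected patches, the pairing
   units that an operator confirms.
2. **Constrained, weighted, hierarchical ICP** — seat each fragment's
   fracture patch onto the matching patch of the base bone with a modified
   iterative-closest-point estimator.
3. **Zippering** — integrate the aligned meshes into a single consensus
   surface by removing redundant triangles, clipping at the common
   boundary, and cleaning sliver triangles.

A procedural phantom generator supplies synthetic fracture cases with known
ground truth, so every stage is testable without patient data.

# Surface classification

Cortical bone images at roughly 700–2500 HU; cancellous bone, exposed only
where the bone broke, is markedly less dense. A vertex is labeled *intact*
when the mean intensity over the surface vertices within
`neighborhood_radius` of it (geodesic distance approximated by shortest
paths along mesh edges) reaches `cortical_low`.

Parameters:

* `cortical_low` (HU, default **700**) — the lower bound of the cortical
  range. The exact refinement threshold used on real CT is scanner- and
  patient-dependent, so it is exposed rather than hard-coded.
* `neighborhood_radius` (mm, default **0**) — averaging radius. Radius 0
  degenerates to per-vertex thresholding; a positive radius emulates the
  robustness that volumetric mask refinement provides, while staying
  purely surface-based (voxel processing is out of scope).

Patches are edge-connected components of fracture vertices; patch area is
the summed area of faces whose three corners all belong to the component,
so isolated vertices carry no area and `min_area` (mm²) discards sliver
components. The labeling is invariant under rigid motion (intensities ride
with vertices) and monotone in the threshold at radius 0.

# The alignment estimator

`icp()` is the package's model-fitting function: it estimates the rigid
transform (rotation $R$, translation $t$) seating a source surface onto a
fixed target, and returns a classed `icp_fit` object with `print`,
`summary`, `coef` (the 4×4 homogeneous matrix), `predict`, `residuals` and
`plot` methods.

Each iteration:

1. **Match** every source point to the nearest point on the *continuous*
   target surface (vertex, edge interior, or face interior), but only
   within the capture range `d` — pairs farther apart are never created.
   The query is exact: a pruned exhaustive scan over triangles whose
   result provably equals brute force, with equidistant ties resolved to
   the lowest face index for determinism.
2. **Exclude boundary pairs**: matches whose target lies on a boundary
   vertex or edge of the target network are removed. Such pairs pull the
   solution sideways — a fragment matched against the rim of the base
   patch would slide off it.
3. **Weight**: binary operator confidence (1 certain / 0 excluded,
   the default) or the legacy scalar mode, the clamped scalar product of
   the target normal with a viewing direction. The scalar mode is a
   range-scanning heuristic with no CT meaning; it is opt-in, with the
   view direction defaulting to the mean source normal.
4. **Solve** the weighted least-squares pose:
   * *point-to-point*: minimize $\sum_i w_i\,\lVert M_i - (R N_i + t)
     \rVert^2$ by the weighted cross-covariance / SVD closed form with
     determinant correction (rotation about the weighted source centroid,
     then centroid-matching translation). This is the exact global
     minimizer.
   * *point-to-plane* (default): minimize
     $\sum_i w_i\,[(R N_i + t - M_i)\cdot n_i]^2$ by small-angle
     linearization of the 6×6 normal equations, re-exponentiating the
     rotation vector (Rodrigues) so the returned rotation is exact. The
     plane variant lets surfaces slide tangentially and converges far
     faster when sliding is needed.

Iteration stops when the relative change of the weighted squared-distance
residual falls below `rel_tol` (default **1e-6**) or at `max_iter`
(default **100**).

**Degeneracy diagnostics.** Perfectly flat or rotationally symmetric
fracture surfaces leave a rigid motion unconstrained. The eigen-spectrum
of the 6×6 point-to-plane system (built about the weighted source
centroid, so rotational and translational scales are comparable) exposes
this: a condition ratio (smallest/largest eigenvalue) below `cond_tol`
(default **1e-6**) yields a `degenerate` verdict naming the unconstrained
direction. The point-to-plane solver refuses to proceed on degenerate
systems; the verdict is also recorded in every fit.

**Capture range.** The paper-style workflow never states an initial `d`;
the default is 10× the median target edge length — scale-free, wide enough
to seed matching after a rough manual placement. For fracture reduction
the practically useful `d` is on the order of the expected residual
displacement.

**Hierarchy.** `hierarchical_icp()` runs coarse-to-fine: the source is
decimated by shortest-edge collapse (one quarter of the vertices per
level, floored so that boundary exclusion cannot starve the solver), each
level warm-starts from the previous transform, and `d` halves per level
down to `d_finest`. The *target* is kept at full resolution: decimating an
open target patch converts most of it into boundary, and the
boundary-exclusion constraint would then remove nearly all pairs. The
wide coarse capture range is what rescues large initial displacements;
the tests include a 15°/8 mm case where a single level with the fine
threshold stalls in a local minimum and the hierarchy does not.

**Why patches, not whole fragments.** Closed fragment meshes must not be
matched whole against a closed base: points just above the cut rim find
false nearest points across the rim, and those pairs make the true pose
unstable (the residual can be *decreased* by sinking the fragment into the
base). Matching the open fracture-patch submeshes restores the geometry
the boundary-exclusion constraint was designed for. `assemble_fragments()`
therefore aligns patch vertices against placed patch submeshes whenever
labelings are provided, processing fragments breadth-first from the base;
pairs that close a cycle are residual-checked, never re-solved (no loop
closure).

# Zippering

`zipper(M, N, d, wall_height, min_edge)` merges two aligned meshes in
three stages.

1. **Redundant-triangle removal** (`remove_redundant`): alternately (N
   first, then M, repeated to a fixed point) delete every triangle whose
   three vertex queries against the other mesh succeed within `d` *and*
   hit only non-boundary points. Face lists shrink; vertex data is
   retained, which is what the optional consensus step later averages
   against.
2. **Clipping and merging** (`extend_wall` + `clip_and_merge`): in 3D the
   two boundaries rarely intersect, so the boundary of N is extended by a
   wall of triangles approximately perpendicular to the surface (each
   boundary vertex swept ±`wall_height`/2 along its vertex normal; 2
   triangles per boundary edge). Boundary edges of M are intersected with
   the wall, every intersection is moved to the nearest position on the
   carrying N boundary edge, and these ordered seam points are inserted
   as new nodes into N's boundary. M triangles lying over the interior of
   N (any vertex — or, for all-rim slivers, the centroid — covered) are
   discarded; coincident vertices across the two sides are welded
   (tolerance 1e-9 mm, so seam vertices are shared, not duplicated), and
   remaining facing gaps are triangulated with greedy strips up to the
   seam, followed by fan-filling of small residual holes. A manifoldness
   guard admits new triangles only while every edge keeps at most two
   incident faces.
3. **Small-triangle cleanup** (`remove_small_triangles`): any vertex
   whose shortest incident edge falls below `min_edge` is deleted with
   its incident triangles by collapsing it into its nearest neighbor
   (which retriangulates the hole as that neighbor's fan);
   seam-introduced vertices are processed first.

Defaults: `wall_height = 4 d` (the boundaries to be captured are within
`d` of each other, so a ±2 d wall is ample) and `min_edge = d / 10`
(slivers created by clipping are far smaller than the matching scale).

Design choices worth making explicit:

* Sliver removal works at whole-triangle granularity followed by gap
  bridging, rather than splitting individual triangles along the seam.
  This guarantees shared seam vertices and watertight results, at the
  cost of moving the seam by at most one triangle — well below `d` in
  all supported uses. The wall-intersection machinery still locates the
  seam ("the red line") exactly, and its points are inserted as mesh
  vertices where they fall inside boundary edges.
* The wall sweeps along the vertex normal (perpendicular to the surface);
  sweeping in-plane would make the wall coplanar with the mesh and
  useless for catching a staggered boundary.
* "Consensus geometry" for unpaired points is under-specified in the
  method's sources; `zipper(..., consensus = TRUE)` implements it as
  halfway averaging of merged vertices toward the retained redundant-zone
  geometry, off by default.
* Known limitation: if both inputs have exactly flush free edges
  (coincident open rims on both meshes — a measure-zero configuration
  for real fragments), a double-covered sliver can survive along the rim.

# The phantom generator

`make_phantom()` builds a closed, manifold long-bone segment: a capped
cylindrical shaft (default radius 10 mm, length 80 mm) flaring smoothly
over the top 30% to 1.6× the shaft radius — the scale of a proximal tibia
segment. The mesh is fully deterministic in its parameters.

`fracture()` splits the phantom by planes or spheres, snapping cut
vertices onto the (possibly curved) level set by bisection, and caps every
cut cross-section. Caps are fans from the rim centroid, refined by two
rounds of subdivision with new vertices projected onto the cut surface and
then displaced by a **deterministic roughness field** (amplitude
`roughness`, default **0.4 mm**, tapered to zero at the rim). Two points
matter here:

* *Roughness is not decoration.* A smooth planar or spherical fracture
  surface leaves in-plane or rotational motion unobservable — exactly the
  degeneracy the diagnostics flag — so pose recovery from a smooth cut is
  ill-posed no matter the estimator. Real fracture surfaces are rough and
  interlocking; 0.4 mm is a conservative interdigitation scale for
  metaphyseal bone. The default case uses a single *curved* (offset
  spherical) cut for the same reason.
* *Caps are exactly complementary.* Both fragments build the identical
  cap from the shared rim (including an orientation-invariant choice of
  subdivision diagonals), so fragment volumes sum to the phantom volume
  to rounding error and seated patches coincide exactly.

`displace()` applies a uniformly sampled rotation (axis uniform on the
sphere, angle uniform up to `max_rot_deg`) about the fragment centroid
plus a uniform translation up to `max_trans_mm`, recording the exact
transforms. The default case magnitudes (5° / 2 mm) represent a
moderately displaced fragment after rough manual pre-positioning; the
recovery tests push to 10°/5 mm and 15°/8 mm. `add_noise()` perturbs
vertices along their normals with i.i.d. normal displacements —
segmentation noise is a surface-location uncertainty, not isotropic
jitter. `synth_intensities()` draws intact-surface intensities uniformly
from 700–2500 HU and fracture-surface intensities from N(350, 100²) HU
clipped at zero: the exposed-cancellous level sits well below the
cortical floor, with enough spread that classification is learnable, not
trivial.

What the generator does *not* emulate: partial-volume blur between
tissues, spatially correlated segmentation artifacts, trabecular texture,
or fragments whose fracture surfaces genuinely interpenetrate. Passing
tests on phantoms therefore demonstrate the correctness of the geometry
and estimation machinery under controlled conditions, not clinical
performance on patient CT.

# Evaluation metrics

`fracture_line_profile()` samples the rim of a fracture patch uniformly
by arc length and measures the unthresholded distance to the base
fracture surface at every sample — the before/after comparison of a
reduction. `degree_of_alignment(d_before, d_after)` is the percent
reduction `100 (d_before − d_after) / d_before`, reported to two
decimals; a reduction from 3.5 mm to 1.09 mm gives 68.86%, from 0.4 mm to
0 mm gives 100%. `classify_alignment()` calls a reduction acceptable when
the mean inter-fragment distance does not exceed a threshold in the
0.1–3 mm range (boundary-inclusive; 0.5, 0.7 and 1 mm are the reporting
defaults), and `alignment_roc()` tabulates that rule over a labeled batch
— the ground-truth labeling on synthetic cases is a tool choice
(e.g. true pose error below a bound), documented wherever used.

# Numerical choices

* Millimetres everywhere; right-handed coordinates; counter-clockwise
  winding means outward normals.
* Vertex normals are the *unweighted* normalized average of incident face
  normals (area weighting deliberately not used).
* Nearest-point ties: lowest face index. Exact (bitwise) ties are
  deterministic; ties created by floating-point noise between equidistant
  faces are resolved within the equidistant set.
* Barycentric classification of query results uses 1e-12; vertex welds
  use 1e-9 mm; both far below any mesh feature scale in mm-sized data.
* Decimation is shortest-edge collapse with link-condition and
  normal-flip guards (quadric error metrics would preserve shape better,
  but coarse ICP warm starts only need approximate geometry).
* All randomness flows through explicit integer seeds; there is no hidden
  random initialization anywhere.

# Test problem sizes

The test and acceptance suites run phantoms at circumferential resolution
16–28 (roughly 700–2600 vertices, fracture patches of 400–800 vertices),
hierarchy checks at resolution 64 (~10,500 vertices), 200-point query
batches against exhaustive oracles, and 10-seed noise sweeps. These sizes
give stable statistics for every property tested while keeping the whole
suite in the low minutes on a single core.

# Limitations

* No global initial pose search: alignment assumes a rough manual
  placement within the capture range, as in the interactive workflow the
  package supports.
* No simultaneous multi-body optimization and no loop closure; cyclic
  pairings are reported as residual checks.
* PLY I/O is ASCII only; STL (ASCII and binary) carries no per-vertex
  attributes, so intensity-bearing meshes must use PLY.
* The zipper's flush-rim corner case described above.
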