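# bonereduce

Virtual reduction of comminuted bone fractures from segmented triangle
meshes: Hounsfield-intensity surface classification, constrained
confidence-weighted hierarchical ICP alignment, and mesh zippering into a
single consensus surface.

## What it does, and for whom

Preoperative planning of complex fractures (the motivating case is a
Schatzker VI tibial plateau fracture) starts from CT-segmented meshes of a
base bone and several displaced fragments. `bonereduce` is for researchers
and engineers building such planning pipelines. It provides the three
computational stages of a semi-automatic virtual reduction:

1. **Classify** each vertex of an intensity-carrying fragment mesh as
   *intact* cortical surface (CT intensities roughly 700–2500 HU) or
   *fracture* surface (exposed cancellous bone, markedly lower HU), and
   extract connected fracture patches — the pairing units an operator
   confirms.
2. **Align** each fragment by fitting a rigid transform with a modified
   iterative closest point (ICP) estimator: matches are made against the
   continuous target surface but only within a capture range *d*; matches
   touching the target boundary are excluded; each pair carries a trust
   weight *wᵢ* ∈ [0, 1]; the pose minimizes either the weighted
   point-to-point objective

   ε = Σᵢ wᵢ ‖Mᵢ − (R Nᵢ + t)‖²

   (solved exactly by weighted SVD) or the point-to-plane objective
   Σᵢ wᵢ [(R Nᵢ + t − Mᵢ)·nᵢ]², which lets surfaces slide tangentially
   and converges much faster. Coarse-to-fine hierarchy halves *d* per
   level; eigen-diagnostics flag degenerate (flat or rotationally
   symmetric) fracture surfaces.
3. **Zipper** the aligned meshes into one surface: alternately remove
   triangles the other mesh already covers, locate the seam by
   intersecting boundary edges with a wall extension perpendicular to the
   surface, clip, weld and bridge up to the seam, and collapse sliver
   triangles.

A procedural phantom generator (`make_phantom()`, `fracture()`,
`displace()`, `synth_intensities()`, `add_noise()`) produces synthetic
fracture cases with exact ground truth, so the whole pipeline runs and is
tested without any patient data. Evaluation metrics implement the
fracture-line distance profile, the percent **degree of alignment**
(3.5 mm → 1.09 mm gives 68.86%), and mean-distance threshold
classification (0.5 / 0.7 / 1 mm).

## Worked example

```r
library(bonereduce)

case <- make_fracture_case(seed = 42)     # phantom + 1 curved cut + displacement
frag <- case$fragments[[2]]$mesh          # displaced fragment (with HU)
base <- case$fragments[[1]]$mesh          # base bone

lab      <- extract_patches(frag, classify_vertices(frag), min_area = 10)
base_lab <- extract_patches(base, classify_vertices(base), min_area = 10)
lab
#> <surface_labeling> 309 intact, 889 fracture vertices
#>   1 fracture patch(es), 0 vertices discarded in 0 small component(s)

fit <- hierarchical_icp(patch_submesh(frag, lab, 1),
                        patch_submesh(base, base_lab, 1),
                        levels = 2, d_finest = 2)
summary(fit)
#> ICP alignment (p2plane)
#>   iterations: 19 (converged)
#>   pose: rotation 2.2360 deg, translation 0.7457 mm
#>   residual: 4.76e-12 mm^2 over 822 pairs (mean distance 3.309e-08 mm)
#>   degeneracy verdict: ok (condition ratio 7.71e-04)
#>   level 1: d = 4 mm, 222 + 889 vertices, 28 iteration(s)
#>   level 2: d = 2 mm, 889 + 889 vertices, 19 iteration(s)

reduced <- predict(fit, frag)
before <- fracture_line_profile(frag,    base, lab, 1, base_lab, 1)
after  <- fracture_line_profile(reduced, base, lab, 1, base_lab, 1)
mean(before$distance); mean(after$distance)
#> [1] 0.242...   # mm, before reduction
#> [1] 3.3e-08    # mm, after reduction
degree_of_alignment(mean(before$distance), mean(after$distance))
#> [1] 100
classify_alignment(mean(after$distance), 0.5)
#> [1] "aligned"

merged <- zipper(intact_shell(base, base_lab),
                 intact_shell(reduced, lab), d = 1)
merged
#> <merge_result> 1473 vertices, 2942 faces; seam of 125 point(s)
#>   counts: redundant_N=0, redundant_M=0, cut=0, created=0, small_removed=21
euler_characteristic(merged$mesh)   # closed genus-0 surface restored
#> [1] 2
```

The fit summary reads like any modelling summary: the estimated pose
(rotation angle and translation norm of the recovered displacement), the
residual of the weighted objective, how many correspondences survived
boundary exclusion, and whether the fracture surface constrained all six
degrees of freedom. The merged mesh is watertight with the phantom's
surface area — the virtual bone is whole again.

Meshes read and write as STL (`read_stl`/`write_stl`, ASCII or binary) and
ASCII PLY with per-vertex `intensity`, `label` and `patch` scalars
(`read_ply`/`write_ply`); transforms as plain-text 4×4 matrices; operator
pairings as YAML (`read_pairs`).

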