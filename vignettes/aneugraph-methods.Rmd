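---
title: "Methods: semantic vessel graphs, inscribed-sphere centerlines and aneurysm morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic vessel graphs, inscribed-sphere centerlines and aneurysm morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and numerical choices
behind `aneugraph`, in the spirit of a methods section: what each stage
assumes, which parameters matter, and what the synthetic validation suite
does and does not demonstrate about clinical data.

## The analysis model

The package operates on a triangulated surface of an aneurysm-bearing
vascular domain, in millimetres, together with a per-edge (or per-face)
segmentation into four classes: the *inlet* vessel (recognisable by its
enlarged calibre), the *aneurysm* sac, *bifurcation* transition zones
(crossovers between vessels, or between a vessel and the sac), and all
remaining *vessels*. Such segmentations typically come from a learned
mesh-segmentation model or from manual annotation; the package itself
supplies only a geometric stand-in (`heuristic_label()`) so the pipeline
can run unassisted.

From the segmentation the package derives an abstract, semantic
representation: connected same-class regions become *segments*, segments
sharing mesh vertices are *connected*, and the resulting part graph is
enriched with anatomical roles and vessel levels. All quantitative
morphometry then reads off this graph plus centerline geometry.

### Segment identifiers

Each segment's numeric id encodes its class in the hundreds digit
(1 inlet, 2 aneurysm, 3 bifurcation, 4 vessel) and a running index in the
lower digits. The running index is assigned deterministically — by
descending edge count, ties broken by the smallest member edge index — so
ids are reproducible across runs; more than 99 segments of one class is an
encoding overflow and an error. Face labelings are converted to edge
labelings first; when the two faces at an edge disagree, the transition
class wins (`BIFURCATION` over `ANEURYSM` over `INLET` over `VESSEL`),
because disagreement zones between parts are precisely what the
bifurcation class models.

### Roles and levels

With the part graph built, roles are refined around the sac: bifurcation
segments adjacent to the aneurysm become the *aneurysm bifurcation*
(at most one; with several candidates the one sharing most vertices with
the sac is chosen and a warning is raised), vessel or inlet segments
touching the sac directly become *aneurysm vessels*, and vessel or inlet
segments adjacent to the aneurysm bifurcation become *parent vessels*
(this assignment wins when both apply). The refinement is idempotent.

Every vessel-like segment receives a *level*: the number of
bifurcation-class segments on the shortest graph path to the aneurysm,
floored at 1; the aneurysm itself is level 0. The floor keeps side-wall
configurations — where a vessel touches the sac with no bifurcation in
between — in the level-1 bin rather than creating a level-0 vessel bin.
Likewise, the bifurcation directly beneath the sac counts toward the
level, so parent vessels are level 1. The inlet segment participates in
per-level statistics like any vessel.

## Centerlines

### The interior field

Centerlines follow the maximal-inscribed-sphere principle: the local
vessel radius at an interior point is the radius of the largest sphere
centred there that fits inside the surface, and a centerline should run
where these spheres are large. The package discretises the interior on a
regular lattice (default pitch: bounding-box diagonal / 90, clamped to
0.25–0.6 mm): sites are lattice nodes that pass a vertical-ray
crossing-parity inside test, each carries the distance to the nearest
surface sample as its inscribed radius, and sites are connected by
26-neighbour adjacency. Surface samples are the mesh vertices, face
centroids, and a barycentric refinement of any face larger than the
lattice pitch — without the refinement, large flat caps would be sampled
too sparsely and inflate radii near them. Open meshes are capped with flat
fans before the inside test.

A centerline between two seed points is the least-cost lattice path with
edge cost (Euclidean length) / (mean endpoint radius), i.e. it minimises
∫ ds/R. The literal alternative — minimising ∫ R ds — would attract paths
to the wall where spheres are small; the inverse-radius form is the
established convention for inscribed-sphere centerlines and is what the
package implements.

### Recentring

A raw lattice path is accurate only to about one cell. Each path point is
therefore pulled onto the local cross-section centre: surface samples in a
thin slab perpendicular to the running tangent (half-width 0.75 pitch) are
projected into the plane and a least-squares (Kasa) circle is fitted;
the point moves to the fitted centre, capped at one pitch per iteration,
for two iterations. The circle fit is exact for a circular ring under any
angular sampling density, unlike a raw centroid. Recentring is skipped
wherever the slab samples do not surround the point (largest angular gap
above ~103°): oblique slices of end caps or junction walls are one-sided
and would drag the point off-axis. On generated tubes this brings the
lateral error from ~0.2 mm (lattice) to below 0.01 mm.

### Per-segment trees

All (inlet → outlet) paths are computed on one shared distance field, with
deterministic backward path reconstruction. Because optimal lattice paths
to different outlets may run along parallel, equal-cost lanes, path
sharing is decided by proximity rather than by site identity: paths count
as shared while each stays within max(2.2 pitch, half the local radius) of
the reference path, and they split into branches where that fails; the
probe points just past a split are single-linkage clustered to group paths
that continue together. Each branch is assigned to the semantic-graph
segment containing the majority of its points (nearest-vertex vote).

### Curvature and torsion

Branches are resampled to a uniform arc-length step (default
min(0.1 mm, length/100) for analytic-quality polylines; 1.0 mm is the
recommendation for lattice-derived branches, where measurement noise at a
0.1 mm step would be amplified by the second and third derivatives),
smoothed with a centred moving average (window 5), and differentiated by
central finite differences: κ = |r′×r″|/|r′|³ and
τ = (r′×r″)·r‴/|r′×r″|². Torsion is reported as 0 where κ < 10⁻⁴ mm⁻¹
(undefined Frenet frame on straight runs) — note that on *nearly* straight
vessels (κ of order 0.01) torsion remains poorly conditioned and its
per-vessel statistics should be read with care. The moving-average edge
effect flattens the curve ends, so the affected boundary values are
replaced by the first fully smoothed interior value. On helix oracles the
estimator converges at second order in the step.

## Outlets

On open meshes, openings are the closed cycles formed by edges with
exactly one incident triangle. On closed meshes, flat caps meet the wall
at dihedral angles near 90°: edges within ±20° of 90° (angle between
incident face normals; 0° = coplanar) are collected, their vertices
clustered by connectivity, and each group that forms a ring passing a
circularity threshold (coefficient of variation of centre distances
≤ 0.15) and a planarity threshold (max plane deviation / equivalent radius
≤ 0.1) is an outlet. The thresholds were fixed once against the synthetic
suite and are exposed as arguments. The opening with the largest
equivalent radius is flagged as the candidate inlet, consistent with the
inlet's enlarged calibre; outward normal orientation uses the surface
centroid as reference. Equivalent radius is √(enclosed planar area / π).

## Cutting and flow extensions

For hemodynamic simulation the vessel ends must be perpendicular to the
local axis, with straight extensions long enough for flow profiles to
develop. At a seed vertex, all mesh points within a neighbourhood (default
3 mm) enter a PCA; the dominant axis is the local vessel direction. The
local centre is *not* the patch centroid — a 3 mm ball on a 4 mm vessel
covers only part of the circumference, and the centroid would sit off-axis
— but the least-squares circle centre of the points projected into the
plane perpendicular to the axis; the local diameter is twice the mean
in-plane distance to that centre. The mesh is cut by the plane through the
centre perpendicular to the axis (crossing triangles are split exactly, so
the rim is planar to machine precision), the side without aneurysm-labelled
elements (or the smaller side) is discarded, and the rim is extruded as a
straight prism by 5 local diameters (configurable; 0 = pure cut). A plane
that produces several cross-section loops — a seed too close to a
bifurcation — is an error rather than a guess.

## Morphometry

Per-vessel metrics are arc-length-weighted summaries (average, min, max,
variance) of radius, curvature and torsion over the branch, restricted to
the vessel's segment extent where a mesh is available. Per-level pooling
weights each vessel equally: the pooled average is the mean of per-vessel
averages, min/max are taken across vessels, and the variance is the
between-vessel variance of per-vessel averages. Levels above `max_level`
(default 4) are omitted, matching the depth to which generated and typical
clinical trees are populated.

The parent-vessel diameter is measured as 2 × mean (or max) inscribed
radius over the parent branch, after excluding (a) one local radius at
each branch end, where inscribed spheres are truncated by the openings
rather than the wall, and (b) every sample whose cross-section slab
contains bifurcation-class wall vertices — the sac widens the vessel
there, and the bifurcations delimit the measurable parent section. The
no-exclusion mode exists purely as a diagnostic; on a host with a widened
zone under the sac it overestimates the diameter by ~10% while the
excluding mode stays within 5% of the nominal calibre.

The neck (ostium) curve is the cycle of vertices shared between the
aneurysm segment and its adjacent bifurcation (or, without a collar,
vessel) segment, ordered along mesh connectivity, with an angular-order
fallback when chord edges make the shared ring non-simple; fragmenting
into several components is an error. The neck plane is the best-fit plane
of the cycle. Shape indices: neck diameter = 2√(planar area/π); height =
maximum signed distance of sac vertices from the neck plane (dome side
positive; vertices far below the plane trigger an irregular-neck warning);
width = maximal caliper of sac vertices in planes parallel to the neck
plane (convex hull of the projection); maximum diameter = largest pairwise
sac vertex distance; aspect ratio = height/neck diameter; size ratio =
height/parent diameter; bottleneck factor = width/neck diameter. All are
rigid-invariant, and the three ratios are scale-free.

## The synthetic generator

The generator builds watertight tubular trees as the zero level set of a
smooth-minimum (log-sum-exp, sharpness = blend_distance/4) union of
capsule-chain distance fields — one per branch, swept along a line, arc or
helix with a constant, tapered or locally bulged radius profile — plus
spheres for an optional sac and bleb. Marching tetrahedra on a uniform
lattice (six tetrahedra per cube around the main diagonal, which makes
neighbouring cubes conforming) extracts a guaranteed-watertight,
edge-manifold surface; triangles are oriented by the field gradient.
The implicit route was chosen over boolean mesh unions precisely because
it is watertight at every bifurcation angle.

Ground-truth labels mirror the class scheme: a face is `ANEURYSM` when its
nearest primitive is the sac or bleb, `BIFURCATION` when a second
primitive lies within `blend_distance` of the nearest (junction zones and
the collar around the sac attachment — except that sac-nearest faces stay
`ANEURYSM`, so the sac/collar interface coincides with the geometric
sac–host intersection, the ostium), `INLET` on the inlet branch and
`VESSEL` elsewhere; single-face islands are absorbed into their
surroundings. The expected semantic graph is enumerated by brute force
from these labels — plain union-find over face adjacency, vertex-wise
contact enumeration, a hand-rolled breadth-first level count —
deliberately independent of the edge-based igraph machinery the pipeline
itself uses. Analytic curvature and torsion are emitted, not measured:
lines (0, 0), arcs (κ, 0), helices (r/(r²+c²), c/(r²+c²)).

Branch attachments are restricted to parent ends (binary junctions) plus
mid-branch side-wall sacs; the inlet is generated with ≥1.3× the daughter
radii so the enlarged-calibre convention holds. `make_cohort()` draws
per-branch curvature from a log-normal baseline LN(log 0.08, 0.4) mm⁻¹ and
torsion from LN(log 0.04, 0.5) mm⁻¹ — chosen once as representative of
cerebral-vessel tortuosity scales — over Y-trees with apex sacs
(daughter radii 1.8–2.2 mm, trunk 1.35× the larger daughter, lengths
11–14 mm, sac radius 2.4–3.0 mm, marching pitch 0.45 mm), with one master
seed and per-case derived streams, so any case is reproducible in
isolation. For exact morphometry oracles the suite additionally includes
an analytically triangulated spherical cap on a flat host patch
(`make_sac_patch()`), where neck circle and cap height have closed forms
untouched by implicit blending.

What the suite emulates: watertight vascular topology, realistic calibres
and tortuosity, apex and side-wall sacs with blebs, label transition
zones. What it does not: imaging noise, segmentation errors beyond the
stand-in labeller, wall irregularity, non-circular lumina, touching or
kissing vessels, and real cohort variability. Passing the suite therefore
demonstrates correctness of the geometry processing, not robustness to
clinical segmentation quality.

## Problem sizes and numerical choices

The validation suite runs 20 trees for graph recovery, lattice pitches of
0.35–0.45 mm for generated meshes (pitch must stay below a quarter of the
smallest branch radius), and two 50-case cohorts for the
curvature-offset recovery, where a +0.05 mm⁻¹ shift injected into one
cohort is recovered by the pipeline's level-1 mean curvature within the
Monte-Carlo confidence interval. These sizes were chosen so the full suite
exercises every stage at meaningful resolution while remaining convenient
to run routinely.

Degenerate inputs are handled explicitly: duplicate vertices are merged at
10⁻⁶ mm on read (STL dialects duplicate per facet); generated meshes merge
at 2×10⁻⁶ mm so file round-trips preserve counts; vertices exactly on a
cut plane are nudged to the discarded side; a whole vertex ring lying
exactly in a cut plane is the common case for swept tubes and is handled
the same way; empty meshes, non-manifold boundaries, unreachable outlets,
missing aneurysm classes and id overflows raise errors that name the
remediation.

## Known limitations

* The interior field is lattice-based; below ~3 sites per radius the
  shortest paths degrade. The default pitch guards against this, but very
  thin vessels (< 1 mm radius) would need a finer pitch and more memory.
* Torsion on nearly straight vessels is ill-conditioned (see above).
* The stand-in labeller is purely geometric: it finds off-branch surface
  (sacs), branch-proximity overlaps (bifurcations) and the inlet branch,
  but cannot reproduce learned segmentation behaviour on irregular
  anatomy; with an apex sac nestled between daughters its accuracy drops
  to ~0.88.
* `refine_roles()` assumes one aneurysm per mesh; extra sac components are
  flagged `aneurysm_secondary` and excluded from role refinement.
* Levels use unweighted shortest graph paths; on graphs with cycles
  (fused vessels) ties could count different bifurcation numbers.
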