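# aneugraph

Semantic vessel graphs, centerlines and morphometry for intracranial
aneurysm surface meshes.

Intracranial aneurysms are saccular outpouchings of cerebral vessel walls;
their rupture risk is commonly assessed through morphological indices such
as the aspect ratio (sac height / neck diameter), size ratio (height /
parent-vessel diameter) and bottleneck factor (width / neck diameter).
Computing these automatically requires separating the sac from the
surrounding vasculature, understanding which vessel is the parent, and
measuring calibres away from the distorted bifurcation zones. `aneugraph`
implements that whole downstream analysis for triangle surface meshes of
the vasculature (mm units) that carry a four-class segmentation — `INLET`,
`ANEURYSM`, `BIFURCATION`, `VESSEL` — per edge or per face:

* **Semantic vessel graph** — connected same-class regions become segments
  with hundreds-digit numeric ids (`4xx` = vessel, `3xx` = bifurcation,
  `2xx` = aneurysm, `1xx` = inlet); segments sharing vertices are
  connected; roles are refined (the bifurcation touching the sac is the
  *aneurysm bifurcation*, vessels attached to it are *parent vessels*,
  vessels touching the sac directly are *aneurysm vessels*); every vessel
  gets a *level* = number of bifurcations between it and the sac.
* **Outlet detection** — boundary loops on open meshes; dihedral-angle +
  circular/planar grouping on closed meshes.
* **Centerlines** — a maximal-inscribed-sphere interior field; paths
  minimize ∫ ds/R so they stay where inscribed spheres are large; branches
  are split at junctions, recentred on the cross-section, and carry
  radius, curvature κ and torsion τ profiles (κ = |r′×r″|/|r′|³,
  τ = (r′×r″)·r‴/|r′×r″|²).
* **Perpendicular cutting and flow extensions** — local PCA frame at a
  seed vertex, cut perpendicular to the vessel axis, straight prismatic
  extrusion of five local diameters for CFD-ready inlets/outlets.
* **Morphometry** — per-level vessel statistics (count, length, radius /
  curvature / torsion summaries), parent-vessel diameter with the
  bifurcation section excluded, neck (ostium) curve extraction, and the
  sac shape indices above.
* **Synthetic generator** — watertight tubular vessel trees (smooth-min
  implicit union + marching tetrahedra) with attachable sacs and blebs and
  complete ground truth: labels, segments, expected graph, analytic
  centerlines with closed-form κ/τ. Every stage of the package is
  validated against it; no clinical data are needed.

A geometric stand-in labeller (`heuristic_label()`) lets the pipeline run
end-to-end on unlabelled meshes; it is explicitly not a learned
segmentation model.

## Worked example

```r
library(aneugraph)

# a Y-shaped tree with an apex sac, plus full ground truth
tr <- make_tree(synthetic_suite()$y_apex)
op <- open_tree_ends(tr)          # open the three terminal ends

# semantic graph from the ground-truth labels
lab  <- convert_labels(op$mesh, op$face_labels)
segs <- split_segments(op$mesh, lab)
g    <- assign_levels(refine_roles(build_part_graph(op$mesh, segs)))
g
#> <vessel_graph> 5 segments, 4 connections
#>   101 INLET (parent_vessel, level 1)
#>   201 ANEURYSM (aneurysm, level 0)
#>   301 BIFURCATION (aneurysm_bifurcation)
#>   401 VESSEL (parent_vessel, level 1)
#>   402 VESSEL (parent_vessel, level 1)
```

The trunk and both daughters sit at level 1 (one bifurcation — the
aneurysm bifurcation — between each of them and the sac), the sac itself
is level 0.

```r
# outlets, centerlines, morphometry
loops   <- find_boundary_loops(op$mesh)
outlets <- lapply(loops, outlet_geometry, mesh = op$mesh)
radii   <- sapply(outlets, `[[`, "equivalent_radius")
for (i in seq_along(outlets)) outlets[[i]]$candidate_inlet <- i == which.max(radii)

tree <- compute_centerline_tree(op$mesh, outlets, graph = g)
tree <- tree_frenet(tree, resample_step = 1.0)

pd <- parent_vessel_diameter(g, tree, mesh = op$mesh)
neck <- extract_neck_curve(op$mesh, lab, g)
aneurysm_shape(op$mesh, neck, pd$value, g)
#> <aneurysm_shape> neck 5.14 mm, height 3.61 mm, width 6.14 mm, max diameter 6.14 mm
#>   aspect ratio 0.70 | size ratio 0.83 | bottleneck factor 1.20
#> Warning message: aneurysm vertices extend beyond the neck plane on both sides (irregular neck)
```

(The warning is expected for an apex sac nestled between two daughter
vessels: part of the sac bulges below the ostium plane.)

Or run everything in one call, with logged stages and a checksummed
artifact manifest:

```r
write_mesh(op$mesh, "tree.ply")
man <- run_pipeline(pipeline_config(mesh = "tree.ply", output_dir = "out", seed = 1))
```

A thin command-line front end with subcommands (`synth`, `validate`,
`label`, `graph`, `outlets`, `centerline`, `cut`, `morpho`, `run`) is
installed at `system.file("cli", "aneugraph.R", package = "aneugraph")`.

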