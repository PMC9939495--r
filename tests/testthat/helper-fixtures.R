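# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(builder)
  .fx[[name]]
}

rownorms <- aneugraph:::rownorms

# boundary-loop outlets with the candidate-inlet flag set
mk_outlets <- function(mesh) {
  loops <- find_boundary_loops(mesh)
  outl <- lapply(loops, outlet_geometry, mesh = mesh)
  radii <- vapply(outl, `[[`, 0, "equivalent_radius")
  for (i in seq_along(outl)) outl[[i]]$candidate_inlet <- i == which.max(radii)
  outl
}

# exact lateral distance from each row of P to the polyline gtp
poly_dist <- function(P, gtp) {
  np <- nrow(gtp)
  aneugraph:::capsule_field(P, gtp[-np, , drop = FALSE], gtp[-1, , drop = FALSE],
                            rep(0, np - 1), rep(0, np - 1))$distance
}

# labels -> refined, levelled semantic graph
build_graph <- function(mesh, face_labels) {
  lab <- convert_labels(mesh, face_labels)
  g <- build_part_graph(mesh, split_segments(mesh, lab))
  if (any(g$nodes$class == "ANEURYSM")) g <- assign_levels(refine_roles(g))
  g
}

# enclosed volume of a watertight mesh, by voxel counting (orientation-free)
mesh_volume <- function(mesh, pitch = 0.25) {
  ext <- apply(mesh$vertices, 2, range)
  lo <- ext[1, ] - pitch
  dims <- as.integer(ceiling((ext[2, ] - ext[1, ]) / pitch)) + 3L
  ins <- aneugraph:::grid_inside(mesh$vertices, mesh$triangles, lo, pitch, dims)
  sum(ins) * pitch^3
}

fx_cyl_open <- function() fixture("cyl_open", make_tube(
  branch_spec("line", length = 20, radius = 2), n_circ = 32, n_axial = 50))

fx_cyl_capped <- function() fixture("cyl_capped", make_tube(
  branch_spec("line", length = 20, radius = 2), n_circ = 32, n_axial = 50,
  capped = TRUE))

fx_arc_capped <- function() fixture("arc_capped", make_tube(
  branch_spec("arc", length = 25, radius = 2, curvature = 0.05),
  n_circ = 32, n_axial = 60, capped = TRUE))

fx_y_apex <- function() fixture("y_apex", make_tree(synthetic_suite()$y_apex))

fx_y_plain <- function() fixture("y_plain", make_tree(synthetic_suite()$y_plain))

fx_sidewall <- function() fixture("sidewall", make_tree(tree_spec(
  list(branch_spec("line", length = 16, radius = 1.5)),
  aneurysm = list(branch = 1, position = 0.5, sac_radius = 3,
                  offset = 1.5 + sqrt(9 - 2.25), azimuth = 0),
  blend_distance = 0.7, voxel_pitch = 0.35)))

fx_sac_patch <- function() fixture("sac_patch", make_sac_patch(3, 1.5))

# centerline tree (+ graph + field) for a generated case, opened at terminals
fx_case_pipeline <- function(name, case, pitch = NULL) fixture(name, {
  g <- build_graph(case$mesh, case$ground_truth$face_labels)
  op <- open_tree_ends(case)
  field <- medial_field(op$mesh, pitch = pitch)
  tree <- compute_centerline_tree(op$mesh, mk_outlets(op$mesh), field = field)
  tree <- assign_tree_segments(tree, g)
  list(graph = g, open = op, field = field, tree = tree)
})
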