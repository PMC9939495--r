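test_that("swept tubes carry exact analytic centerline ground truth", {
  tb <- fx_cyl_open()
  expect_equal(length(find_boundary_loops(tb$mesh)), 2L)
  expect_true(all(tb$ground_truth$centerlines[[1]]$radius == 2))

  hx <- make_tube(branch_spec("helix", length = 15, radius = 1.5,
                              helix_radius = 2, helix_pitch = 1), 16, 20)
  gt <- hx$ground_truth$centerlines[[1]]
  expect_equal(unique(gt$curvature), 2 / 5)  # r / (r^2 + c^2)
  expect_equal(unique(gt$torsion), 1 / 5)    # c / (r^2 + c^2)

  ac <- make_tube(branch_spec("arc", length = 20, radius = 1.5,
                              curvature = 0.1), 16, 20)
  expect_equal(unique(ac$ground_truth$centerlines[[1]]$curvature), 0.1)
  expect_equal(unique(ac$ground_truth$centerlines[[1]]$torsion), 0)
})

test_that("a sweep whose radius exceeds the curve's radius of curvature errors", {
  expect_error(make_tube(branch_spec("arc", length = 10, radius = 6,
                                     curvature = 0.2), 16, 20),
               "self-intersecting")
})

test_that("a single-branch tree is watertight, all-INLET, with a one-node graph", {
  tr <- make_tree(synthetic_suite()$single_plain)
  expect_true(validate_mesh(tr$mesh)$is_watertight)
  expect_true(all(tr$ground_truth$face_labels$labels == "INLET"))
  expect_equal(nrow(tr$ground_truth$graph$nodes), 1L)
})

test_that("every generated suite tree is watertight with partitioning labels", {
  for (nm in c("y_apex", "y_daughter_sidewall", "five_apex")) {
    tr <- if (nm == "y_apex") fx_y_apex() else make_tree(synthetic_suite()[[nm]])
    expect_true(validate_mesh(tr$mesh)$is_watertight, info = nm)
    labs <- tr$ground_truth$face_labels$labels
    expect_equal(length(labs), n_faces(tr$mesh), info = nm)
    expect_false(anyNA(labs), info = nm)
    # every bifurcation component touches >= 2 other components (>= 1 when
    # it is the collar of a side-wall sac on a single host)
    gg <- tr$ground_truth$graph
    for (b in which(gg$nodes$class == "BIFURCATION")) {
      deg <- sum(gg$edges == b)
      expect_gte(deg, 2)
    }
  }
})

test_that("apex-sac Y-tree ground truth matches brute-force component enumeration", {
  tr <- fx_y_apex()
  gg <- tr$ground_truth$graph
  # 5 parts: inlet trunk, two daughters, the aneurysm bifurcation, the sac
  expect_equal(sort(gg$nodes$class),
               sort(c("INLET", "VESSEL", "VESSEL", "BIFURCATION", "ANEURYSM")))
  expect_equal(nrow(gg$edges), 4L)
  # brute-force check: component count per class from the face labels
  labs <- as.character(tr$ground_truth$face_labels$labels)
  ef <- tr$mesh$edge_faces
  inner <- which(!is.na(ef[, 2]))
  same <- inner[labs[ef[inner, 1]] == labs[ef[inner, 2]]]
  g <- igraph::graph_from_edgelist(ef[same, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(labs) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(labs)]
  expect_equal(length(unique(comp)), nrow(gg$nodes))
})

test_that("a sac-free tree of 3 junctions has 3 bifurcation components", {
  tr <- make_tree(tree_spec(synthetic_suite()$seven_apex$branches,
                            blend_distance = 0.9, voxel_pitch = 0.4))
  gg <- tr$ground_truth$graph
  expect_equal(sum(gg$nodes$class == "BIFURCATION"), 3L)
})

test_that("cohort generation is byte-identical under a fixed seed", {
  a <- make_cohort(2, seed = 7)
  b <- make_cohort(2, seed = 7)
  for (i in 1:2) {
    expect_identical(a[[i]]$mesh$vertices, b[[i]]$mesh$vertices)
    expect_identical(a[[i]]$mesh$triangles, b[[i]]$mesh$triangles)
    expect_identical(as.character(a[[i]]$ground_truth$face_labels$labels),
                     as.character(b[[i]]$ground_truth$face_labels$labels))
  }
})

test_that("invalid tree specifications are rejected before meshing", {
  expect_error(tree_spec(list(branch_spec("line", length = 10, radius = 2)),
                         inlet_branch = 3), "out of range")
  expect_error(tree_spec(list(branch_spec("line", length = 10, radius = 2)),
                         aneurysm = list(branch = 1, position = 1.5,
                                         sac_radius = 2)),
               "within the branch domain")
  expect_error(make_tree(tree_spec(list(branch_spec("line", length = 10,
                                                    radius = 1)),
                                   voxel_pitch = 0.4)),
               "pitch too coarse")
})

test_that("ground-truth exports land in the package file contracts", {
  tr <- fx_y_apex()
  d <- tempfile("gt")
  paths <- write_ground_truth(list(mesh = tr$mesh,
                                   ground_truth = tr$ground_truth), d)
  expect_true(all(file.exists(paths)))
  m2 <- read_mesh(paths[["mesh"]])
  expect_equal(n_faces(m2), n_faces(tr$mesh))
  cl <- read.csv(paths[["centerlines"]])
  expect_equal(sort(unique(cl$branch_id)), 1:3)
  g <- igraph::read_graph(paths[["graph"]], format = "graphml")
  expect_equal(igraph::vcount(g), nrow(tr$ground_truth$graph$nodes))
})
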