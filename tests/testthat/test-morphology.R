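analytic_branch <- function(kind = "line", length = 20, radius = 2, n = 200, ...) {
  b <- branch_spec(kind, length = length, radius = radius, ...)
  b$origin <- c(0, 0, 0); b$frame <- list(t = c(0, 0, 1), n = c(1, 0, 0))
  s <- seq(0, length, length.out = n)
  ev <- aneugraph:::curve_eval(b, s)
  r <- aneugraph:::branch_radius(b, s)
  frenet_geometry(aneugraph:::new_centerline(ev$points, r))
}

test_that("vessel metrics reproduce constant, helical and tapered branches", {
  cl <- analytic_branch("line", 20, 2)
  m <- vessel_metrics(cl)
  expect_lt(abs(m$length - 20) / 20, 0.01)
  expect_lt(abs(m$radius[["avg"]] - 2), 1e-6)
  expect_lt(m$radius[["var"]], 1e-9)
  expect_lt(m$curvature[["avg"]], 1e-8)

  hx <- analytic_branch("helix", 15, 2, helix_radius = 2, helix_pitch = 1)
  mh <- vessel_metrics(hx)
  expect_lt(abs(mh$curvature[["avg"]] - 0.4) / 0.4, 0.02)
  expect_lt(abs(mh$torsion[["avg"]] - 0.2) / 0.2, 0.05)
  expect_lt(mh$curvature[["var"]], 1e-4)

  tp <- analytic_branch("line", 20, c(2, 1))
  mt <- vessel_metrics(tp)
  expect_lt(abs(mt$radius[["avg"]] - 1.5), 0.02)
  expect_lt(abs(mt$radius[["min"]] - 1.0), 0.02)
  expect_lt(abs(mt$radius[["max"]] - 2.0), 0.02)

  expect_error(vessel_metrics(aneugraph:::new_centerline(cl$points[1:4, ],
                                                         cl$radius[1:4])),
               "undersampled|too few|curvature")
})

test_that("per-level statistics count vessels as the level rule demands", {
  tr <- fx_y_apex()
  cp <- fx_case_pipeline("pipe_y_apex", tr, pitch = 0.4)
  tree <- tree_frenet(cp$tree, resample_step = 1.0, smoothing_window = 5)
  pls <- per_level_stats(cp$graph, tree, mesh = tr$mesh)
  expect_equal(pls$vessel_count[pls$level == 1], 3L)
  expect_false(any(pls$level >= 2))

  tr7 <- fixture("seven_apex_tree", make_tree(synthetic_suite()$seven_apex))
  cp7 <- fx_case_pipeline("pipe_seven", tr7, pitch = 0.42)
  tree7 <- tree_frenet(cp7$tree, resample_step = 1.0, smoothing_window = 5)
  pls7 <- per_level_stats(cp7$graph, tree7, mesh = tr7$mesh)
  expect_equal(pls7$vessel_count[pls7$level == 1], 3L)
  expect_equal(pls7$vessel_count[pls7$level == 2], 4L)
})

test_that("parent-vessel diameter excludes the widened bifurcation section", {
  spec <- tree_spec(
    list(branch_spec("line", length = 16, radius = 1.5,
                     bulge = list(amplitude = 1.0, position = 8, width = 0.8))),
    aneurysm = list(branch = 1, position = 0.5, sac_radius = 3,
                    offset = 2.5 + sqrt(9 - 2.25), azimuth = 0),
    blend_distance = 0.8, voxel_pitch = 0.35)
  tr <- fixture("bulge_tree", make_tree(spec))
  cp <- fx_case_pipeline("pipe_bulge", tr, pitch = 0.35)
  pd_on <- parent_vessel_diameter(cp$graph, cp$tree, mesh = tr$mesh)
  pd_off <- parent_vessel_diameter(cp$graph, cp$tree,
                                   exclude_bifurcations = FALSE, mesh = tr$mesh)
  expect_lt(abs(pd_on$value - 3.0) / 3.0, 0.05)
  expect_gt(pd_off$value, 3.2)
})

test_that("maximum-mode diameter reports the widest retained cross-section", {
  spec <- tree_spec(
    list(branch_spec("line", length = 24, radius = c(2, 1.6))),
    aneurysm = list(branch = 1, position = 0.75, sac_radius = 2.6,
                    offset = 1.75 + 2.0, azimuth = 0),
    blend_distance = 0.8, voxel_pitch = 0.4)
  tr <- fixture("taper_tree", make_tree(spec))
  cp <- fx_case_pipeline("pipe_taper", tr, pitch = 0.4)
  pd <- parent_vessel_diameter(cp$graph, cp$tree, mode = "maximum",
                               mesh = tr$mesh)
  expect_lt(abs(pd$value - 4.0) / 4.0, 0.05)
})

test_that("the spherical-cap shape indices follow closed-form geometry", {
  p <- fx_sac_patch()
  lab <- convert_labels(p$mesh, p$face_labels)
  g <- refine_roles(build_part_graph(p$mesh, split_segments(p$mesh, lab)))
  neck <- extract_neck_curve(p$mesh, lab, g)
  shape <- aneurysm_shape(p$mesh, neck, 3.0, g)
  h_true <- 3 + sqrt(9 - 1.5^2)
  expect_lt(abs(shape$height - h_true) / h_true, 0.05)
  expect_lt(abs(shape$aspect_ratio - h_true / 3) / (h_true / 3), 0.05)
  expect_lt(abs(shape$size_ratio - h_true / 3) / (h_true / 3), 0.05)
  expect_lt(abs(shape$width - 6) / 6, 0.05)
  expect_lt(abs(shape$max_diameter - 6) / 6, 0.05)
  # the ratio identities hold exactly
  expect_lt(abs(shape$aspect_ratio - shape$height / shape$neck_diameter), 1e-9)
  expect_lt(abs(shape$bottleneck_factor - shape$width / shape$neck_diameter), 1e-9)
})

test_that("a hemispherical sac has bottleneck factor one", {
  h <- fixture("hemi_patch", make_sac_patch(2, 1.9999))
  lab <- convert_labels(h$mesh, h$face_labels)
  g <- refine_roles(build_part_graph(h$mesh, split_segments(h$mesh, lab)))
  neck <- extract_neck_curve(h$mesh, lab, g)
  shape <- aneurysm_shape(h$mesh, neck, 4.0, g)
  expect_lt(abs(shape$height - 2.0) / 2.0, 0.05)
  expect_lt(abs(shape$width - 4.0) / 4.0, 0.05)
  expect_lt(abs(shape$bottleneck_factor - 1.0), 0.05)
})

test_that("shape indices are rigid-invariant and ratios are scale-free", {
  p <- fx_sac_patch()
  lab <- convert_labels(p$mesh, p$face_labels)
  run <- function(mesh) {
    g <- refine_roles(build_part_graph(mesh, split_segments(mesh, lab)))
    neck <- extract_neck_curve(mesh, lab, g)
    aneurysm_shape(mesh, neck, 3.0, g)
  }
  s0 <- run(p$mesh)
  set.seed(9)
  A <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(A) < 0) A[, 1] <- -A[, 1]
  mr <- surface_mesh(sweep(p$mesh$vertices %*% t(A), 2, c(4, -7, 2), `+`),
                     p$mesh$triangles, merge_tolerance = 0)
  s1 <- run(mr)
  for (f in c("neck_diameter", "height", "width", "max_diameter",
              "aspect_ratio", "bottleneck_factor"))
    expect_lt(abs(s1[[f]] - s0[[f]]) / abs(s0[[f]]), 1e-6)

  ms <- surface_mesh(p$mesh$vertices * 2.5, p$mesh$triangles,
                     merge_tolerance = 0)
  g2 <- refine_roles(build_part_graph(ms, split_segments(ms, lab)))
  neck2 <- extract_neck_curve(ms, lab, g2)
  s2 <- aneurysm_shape(ms, neck2, 2.5 * 3.0, g2)
  expect_lt(abs(s2$height - 2.5 * s0$height) / s0$height, 1e-9)
  expect_lt(abs(s2$aspect_ratio - s0$aspect_ratio), 1e-9)
  expect_lt(abs(s2$size_ratio - s0$size_ratio), 1e-9)
  expect_lt(abs(s2$bottleneck_factor - s0$bottleneck_factor), 1e-9)
})
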