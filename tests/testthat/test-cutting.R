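test_that("the local PCA frame recovers the cylinder axis and diameter", {
  m <- fx_cyl_open()$mesh
  seed <- which.min(abs(m$vertices[, 3] - 10))
  fr <- local_frame(m, seed, neighborhood_radius = 3)  # the 3 mm default
  expect_lt(acos(abs(sum(fr$axes[, 1] * c(0, 0, 1)))) * 180 / pi, 2)
  expect_lt(abs(fr$local_diameter - 4) / 4, 0.05)
  expect_lt(rownorms(matrix(fr$center[1:2], 1)), 0.2)  # centre on the axis
  expect_false(fr$isotropic)
  # orthonormal axes
  g <- t(fr$axes) %*% fr$axes
  expect_lt(max(abs(g - diag(3))), 1e-9)
})

test_that("the frame tolerates bent tubes within the stated diameter bound", {
  ta <- fx_arc_capped()$mesh
  seed <- which.min(rownorms(sweep(ta$vertices, 2,
                                   fx_arc_capped()$ground_truth$centerlines[[1]]$points[30, ] +
                                     c(2, 0, 0))))
  fr <- local_frame(ta, seed, 3)
  expect_lt(abs(fr$local_diameter - 4) / 4, 0.10)
})

test_that("degenerate neighbourhoods are rejected or flagged", {
  m <- fx_cyl_open()$mesh
  expect_error(local_frame(m, 1, neighborhood_radius = 0.05), "neighborhood")
  # a flat disc has no dominant direction
  p <- make_sac_patch(3, 1.5, patch_radius = 8)
  far <- which(rownorms(p$mesh$vertices[, 1:2, drop = FALSE]) > 5 &
                 abs(p$mesh$vertices[, 3]) < 1e-9)[1]
  expect_warning(local_frame(p$mesh, far, 2.5), "isotropic")
})

test_that("cut and extrude places a planar rim at factor x diameter along pc1", {
  m <- fx_cyl_open()$mesh
  seed <- which.min(abs(m$vertices[, 3] - 10))
  fr <- local_frame(m, seed, 3)
  for (fac in c(0, 1, 5)) {
    cut <- cut_and_extrude(m, fr, fac)
    expect_true(validate_mesh(cut)$is_edge_manifold)
    loops <- find_boundary_loops(cut)
    expect_equal(length(loops), 2L)  # open-end replaced, count preserved
    dists <- vapply(loops, function(lp) {
      o <- outlet_geometry(lp, mesh = cut)
      abs(sum((o$center - fr$center) * fr$axes[, 1]))
    }, 0)
    new_rim <- which.min(abs(dists - fac * fr$local_diameter))
    o <- outlet_geometry(loops[[new_rim]], mesh = cut)
    expect_lt(abs(dists[new_rim] - fac * fr$local_diameter),
              0.01 * max(fr$local_diameter, 1))
    expect_lt(o$planarity * o$equivalent_radius, 1e-3 * fr$local_diameter)
    expect_gt(abs(sum(o$normal * fr$axes[, 1])), cos(1 * pi / 180))
  }
})

test_that("cutting a bent tube near its end stays edge-manifold", {
  ta <- fx_arc_capped()
  gt <- ta$ground_truth$centerlines[[1]]
  seed <- which.min(rownorms(sweep(ta$mesh$vertices, 2,
                                   gt$points[45, ] + c(0, 2, 0))))
  fr <- local_frame(ta$mesh, seed, 3)
  n_before <- length(find_boundary_loops(ta$mesh))
  cut <- cut_and_extrude(ta$mesh, fr, 5)
  expect_true(validate_mesh(cut)$is_edge_manifold)
  expect_equal(length(find_boundary_loops(cut)), n_before + 1L)
})

test_that("enclosed volume grows monotonically with the extrusion factor", {
  m <- fx_cyl_open()$mesh
  seed <- which.min(abs(m$vertices[, 3] - 10))
  fr <- local_frame(m, seed, 3)
  vols <- vapply(c(0, 1, 3, 5), function(fac) {
    mesh_volume(cap_boundary_loops(cut_and_extrude(m, fr, fac)))
  }, 0)
  expect_true(all(diff(vols) > 0))
})

test_that("a plane missing the mesh or crossing a bifurcation is refused", {
  m <- fx_cyl_open()$mesh
  seed <- which.min(abs(m$vertices[, 3] - 10))
  fr <- local_frame(m, seed, 3)
  fr2 <- fr
  fr2$center <- c(50, 50, 50)
  expect_error(cut_and_extrude(m, fr2, 5), "misses")
  # seed near the junction of a Y-tree: several cross-section loops
  tr <- fx_y_plain()
  apex <- c(0, 0, 12)
  seedy <- which.min(rownorms(sweep(tr$mesh$vertices, 2, apex + c(0, 2.8, 0))))
  fry <- suppressWarnings(local_frame(tr$mesh, seedy, 3.5))
  fry$axes <- diag(3)[, c(3, 1, 2)]  # cut perpendicular to the trunk axis
  fry$center <- apex + c(0, 0, 4)    # both daughters cross this plane
  expect_error(cut_and_extrude(tr$mesh, fry, 5), "loops")
})
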