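test_that("boundary loops are found exactly on closed, open and tree meshes", {
  expect_equal(length(find_boundary_loops(fx_cyl_capped()$mesh)), 0L)
  loops <- find_boundary_loops(fx_cyl_open()$mesh)
  expect_equal(length(loops), 2L)
  expect_true(all(vapply(loops, function(l) length(l$vertex_cycle), 0L) == 32L))
  op <- open_tree_ends(fx_y_plain())
  expect_equal(length(find_boundary_loops(op$mesh)), 3L)
})

test_that("outlet geometry recovers circles, tolerates noise, flags ellipses", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- cbind(2 * cos(th), 2 * sin(th), 0)
  o <- outlet_geometry(circ)
  expect_lt(abs(o$equivalent_radius - 2), 0.02)
  expect_lt(o$planarity, 1e-9)
  expect_lt(o$circularity, 1e-9)

  set.seed(1)
  noisy <- circ + cbind(0, 0, runif(64, -0.1, 0.1))
  on <- outlet_geometry(noisy)
  expect_lt(on$planarity, 0.1)
  expect_gt(on$planarity, 0.01)

  ell <- cbind(2 * cos(th), 1 * sin(th), 0)
  oe <- outlet_geometry(ell)
  expect_lt(abs(oe$equivalent_radius - sqrt(2)), 0.02)
  expect_gt(oe$circularity, 0.15)

  expect_error(outlet_geometry(cbind(1:5, 1:5, 1:5)), "collinear")
})

test_that("dihedral-angle detection finds flat caps and nothing on smooth surfaces", {
  outs <- detect_closed_outlets(fx_cyl_capped()$mesh)
  expect_equal(length(outs), 2L)
  dt <- sum(outs[[1]]$normal * outs[[2]]$normal)
  expect_lt(dt, -cos(2 * pi / 180))  # antiparallel within 2 degrees
  expect_equal(sum(vapply(outs, function(o) o$candidate_inlet, TRUE)), 1L)

  sphere <- make_tree(tree_spec(list(branch_spec("line", length = 0.5,
                                                 radius = 3)),
                                voxel_pitch = 0.3))
  expect_equal(length(detect_closed_outlets(sphere$mesh)), 0L)
})

test_that("capping open rims and re-detecting recovers the open-mode outlets", {
  op <- open_tree_ends(fx_y_plain())
  open_outlets <- mk_outlets(op$mesh)
  capped <- cap_boundary_loops(op$mesh)
  expect_true(validate_mesh(capped)$is_watertight)
  closed_outlets <- detect_closed_outlets(capped, angle_tolerance = 20)
  expect_equal(length(closed_outlets), length(open_outlets))
  # same centers within mesh resolution, same radii within 10%
  oc <- do.call(rbind, lapply(open_outlets, `[[`, "center"))
  cc <- do.call(rbind, lapply(closed_outlets, `[[`, "center"))
  nn <- RANN::nn2(oc, cc, k = 1)
  expect_lt(max(nn$nn.dists), 2 * op$ground_truth$voxel_pitch)
  for (i in seq_along(closed_outlets)) {
    r_open <- open_outlets[[nn$nn.idx[i, 1]]]$equivalent_radius
    expect_lt(abs(closed_outlets[[i]]$equivalent_radius - r_open) / r_open, 0.15)
  }
})

test_that("capped tree outlets match the generator branch end radii within 10%", {
  op <- open_tree_ends(fx_y_plain())
  outl <- mk_outlets(op$mesh)
  term <- op$terminals
  for (o in outl) {
    nn <- which.min(rownorms(sweep(as.matrix(term[, c("x", "y", "z")]), 2,
                                   o$center)))
    expect_lt(abs(o$equivalent_radius - term$radius[nn]) / term$radius[nn], 0.10)
  }
})
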