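test_that("the inscribed-sphere field measures tube and sphere radii", {
  fld <- fixture("field_cyl", medial_field(fx_cyl_capped()$mesh, pitch = 0.4))
  # interior sites (float-exact wall sites aside) pass the inside test
  firm <- fld$radii > fld$pitch / 2
  expect_true(all(mesh_contains(fx_cyl_capped()$mesh,
                                fld$sites[firm, , drop = FALSE])))
  expect_lt(abs(max(fld$radii) - 2) / 2, 0.05)
  # sites within half a cell of the axis carry the full inscribed radius
  near_axis <- rownorms(fld$sites[, 1:2, drop = FALSE]) < fld$pitch / 2
  interior <- abs(fld$sites[, 3] - 10) < 7
  expect_lt(abs(median(fld$radii[near_axis & interior]) - 2) / 2, 0.05)

  sphere <- make_tree(tree_spec(list(branch_spec("line", length = 0.4,
                                                 radius = 5)),
                                voxel_pitch = 0.45))
  flds <- medial_field(sphere$mesh, pitch = 0.45)
  expect_lt(abs(max(flds$radii) - 5) / 5, 0.05)
})

test_that("junction inscribed spheres exceed the daughter radii", {
  cp <- fx_case_pipeline("pipe_y_plain", fx_y_plain(), pitch = 0.4)
  apex <- c(0, 0, 12)
  near <- rownorms(sweep(cp$field$sites, 2, apex)) < 2.5
  expect_gt(max(cp$field$radii[near]), 2.0)  # daughters have radius 2
})

test_that("the cylinder centerline stays within 5% of the tube radius from the axis", {
  fld <- fixture("field_cyl", medial_field(fx_cyl_capped()$mesh, pitch = 0.4))
  cl <- compute_centerline(fld, c(0, 0, 0.5), c(0, 0, 19.5))
  expect_lt(max(rownorms(cl$points[, 1:2, drop = FALSE])), 0.05 * 2)
  # inscribed-sphere consistency: interior points, stored radius honest
  expect_true(all(mesh_contains(fx_cyl_capped()$mesh, cl$points)))
  mid <- cl$arclength > 3 & cl$arclength < max(cl$arclength) - 3
  expect_lt(max(abs(cl$radius[mid] - 2) / 2), 0.10)
})

test_that("the arc-tube centerline matches the analytic sweep in place and length", {
  ta <- fx_arc_capped()
  gt <- ta$ground_truth$centerlines[[1]]
  fld <- medial_field(ta$mesh, pitch = 0.4)
  cl <- compute_centerline(fld, gt$points[3, ], gt$points[58, ])
  expect_lt(max(poly_dist(cl$points, gt$points)), 0.05 * 2)
  L_true <- gt$arclength[58] - gt$arclength[3]
  expect_lt(abs(max(cl$arclength) - L_true) / L_true, 0.03)
})

test_that("the centerline of a sac-bearing host does not enter the sac", {
  tr <- fx_sidewall()
  op <- open_tree_ends(tr)
  fld <- medial_field(op$mesh, pitch = 0.35)
  term <- op$terminals
  cl <- compute_centerline(fld,
                           as.numeric(term[1, c("x", "y", "z")]),
                           as.numeric(term[2, c("x", "y", "z")]))
  # every path point stays inside the host tube (axis = z at x=y=0)
  expect_lt(max(rownorms(cl$points[, 1:2, drop = FALSE])), 1.5)
})

test_that("per-segment centerline trees split at junctions and cover all outlets", {
  cp <- fx_case_pipeline("pipe_y_plain", fx_y_plain(), pitch = 0.4)
  expect_equal(length(cp$tree$branches), 3L)
  expect_gte(nrow(cp$tree$junction_points), 1L)
  # trunk shared prefix has positive length
  lens <- vapply(cp$tree$branches, function(b) max(b$arclength), 0)
  expect_true(all(lens > 5))

  # a single tube yields one branch and no junctions
  fld <- fixture("field_cyl", medial_field(fx_cyl_capped()$mesh, pitch = 0.4))
  outl <- detect_closed_outlets(fx_cyl_capped()$mesh)
  tt <- compute_centerline_tree(fx_cyl_capped()$mesh, outl, field = fld)
  expect_equal(length(tt$branches), 1L)
  expect_equal(nrow(tt$junction_points), 0L)
})

test_that("every ground-truth branch is matched 1:1 within a voxel", {
  tr <- make_tree(synthetic_suite()$seven_apex)
  cp <- fx_case_pipeline("pipe_seven", tr, pitch = 0.42)
  op <- cp$open
  pitch_gt <- tr$ground_truth$voxel_pitch
  gts <- tr$ground_truth$centerlines
  # junction points of the construction: each branch start that has a parent
  junctions <- do.call(rbind, lapply(tr$ground_truth$branches, function(b)
    if (!is.na(b$parent)) b$origin else NULL))
  term <- op$terminals
  match_of <- integer(length(gts))
  for (gi in seq_along(gts)) {
    g <- gts[[gi]]
    keep <- rep(TRUE, nrow(g$points))
    for (ji in seq_len(nrow(junctions)))  # exclude bifurcation zones
      keep <- keep & rownorms(sweep(g$points, 2, junctions[ji, ])) >
        1.3 * max(g$radius)
    for (ti in seq_len(nrow(term))) {     # exclude opened rims
      e <- as.numeric(term[ti, c("x", "y", "z")])
      keep <- keep & rownorms(sweep(g$points, 2, e)) > 2 * pitch_gt
    }
    if (!is.null(tr$ground_truth$sac))    # exclude the sac collar zone
      keep <- keep & rownorms(sweep(g$points, 2,
                                    tr$ground_truth$sac$host_point)) >
        1.3 * max(g$radius)
    ds <- vapply(cp$tree$branches, function(b)
      max(poly_dist(g$points[keep, , drop = FALSE], b$points)), 0)
    expect_lt(min(ds), pitch_gt)
    match_of[gi] <- which.min(ds)
  }
  expect_equal(sort(unique(match_of)), seq_along(cp$tree$branches))
})

test_that("Frenet invariants hit the helix, arc and line closed forms", {
  hx <- branch_spec("helix", length = 15, radius = 2, helix_radius = 2,
                    helix_pitch = 1)
  hx$origin <- c(0, 0, 0); hx$frame <- list(t = c(0, 0, 1), n = c(1, 0, 0))
  ev <- aneugraph:::curve_eval(hx, seq(0, 15, length.out = 200))
  f <- frenet_geometry(aneugraph:::new_centerline(ev$points, rep(2, 200)))
  expect_lt(abs(mean(f$curvature) - 0.4) / 0.4, 0.02)
  expect_lt(abs(mean(f$torsion) - 0.2) / 0.2, 0.05)

  ln <- cbind(0, 0, seq(0, 20, length.out = 150))
  fl <- frenet_geometry(aneugraph:::new_centerline(ln, rep(1, 150)))
  expect_lt(max(fl$curvature), 1e-8)
  expect_lt(max(abs(fl$torsion)), 1e-8)

  ab <- branch_spec("arc", length = 20, radius = 2, curvature = 0.1)
  ab$origin <- c(0, 0, 0); ab$frame <- list(t = c(0, 0, 1), n = c(1, 0, 0))
  ev <- aneugraph:::curve_eval(ab, seq(0, 20, length.out = 200))
  fa <- frenet_geometry(aneugraph:::new_centerline(ev$points, rep(2, 200)))
  expect_lt(abs(mean(fa$curvature) - 0.1) / 0.1, 0.02)
  expect_lt(mean(abs(fa$torsion)), 1e-3)
})

test_that("curvature and torsion are invariant under rigid transforms", {
  hx <- branch_spec("helix", length = 15, radius = 2, helix_radius = 2,
                    helix_pitch = 1)
  hx$origin <- c(0, 0, 0); hx$frame <- list(t = c(0, 0, 1), n = c(1, 0, 0))
  ev <- aneugraph:::curve_eval(hx, seq(0, 15, length.out = 150))
  f0 <- frenet_geometry(aneugraph:::new_centerline(ev$points, rep(2, 150)))
  set.seed(42)
  A <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(A) < 0) A[, 1] <- -A[, 1]
  shift <- c(5, -3, 11)
  pts2 <- sweep(ev$points %*% t(A), 2, shift, `+`)
  f1 <- frenet_geometry(aneugraph:::new_centerline(pts2, rep(2, 150)))
  expect_lt(max(abs(f0$curvature - f1$curvature)), 1e-6)
  expect_lt(max(abs(f0$torsion - f1$torsion)), 1e-6)
})

test_that("curvature error shrinks at first order or better as the step halves", {
  hx <- branch_spec("helix", length = 15, radius = 2, helix_radius = 2,
                    helix_pitch = 1)
  hx$origin <- c(0, 0, 0); hx$frame <- list(t = c(0, 0, 1), n = c(1, 0, 0))
  errs <- vapply(c(0.2, 0.1, 0.05), function(h) {
    ev <- aneugraph:::curve_eval(hx, seq(0, 15, by = h / 2))
    f <- frenet_geometry(aneugraph:::new_centerline(ev$points,
                                                    rep(2, nrow(ev$points))),
                         resample_step = h)
    abs(mean(f$curvature) - 0.4)
  }, 0)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders >= 1))
})
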