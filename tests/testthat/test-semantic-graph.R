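test_that("segments get hundreds-digit ids in deterministic order", {
  m <- fx_cyl_open()$mesh
  all_vessel <- edge_labeling(rep("VESSEL", n_edges(m)), "edge", mesh = m)
  segs <- split_segments(m, all_vessel)
  expect_equal(length(segs), 1L)
  expect_equal(segs[[1]]$numeric_id, 401L)

  # two VESSEL tube halves separated by a BIFURCATION band
  mid_z <- (m$vertices[m$edges[, 1], 3] + m$vertices[m$edges[, 2], 3]) / 2
  lab <- ifelse(mid_z < 9, "VESSEL", ifelse(mid_z < 11, "BIFURCATION", "VESSEL"))
  segs2 <- split_segments(m, edge_labeling(lab, "edge", mesh = m))
  expect_setequal(vapply(segs2, `[[`, 0L, "numeric_id"), c(401L, 402L, 301L))
  # 401 is the larger vessel component
  sizes <- vapply(segs2, function(s) length(s$edge_set), 0L)
  ids <- vapply(segs2, `[[`, 0L, "numeric_id")
  expect_gte(sizes[ids == 401L], sizes[ids == 402L])

  # partition: every edge in exactly one segment, ids decode to the class
  got <- sort(unlist(lapply(segs2, `[[`, "edge_set")))
  expect_identical(got, seq_len(n_edges(m)))
  for (s in segs2)
    expect_equal(unname(aneugraph:::.class_code[[s$class]]),
                 s$numeric_id %/% 100L)
})

test_that("more than 99 components of one class overflow the id encoding", {
  m <- fx_cyl_open()$mesh
  lab <- rep("BIFURCATION", n_edges(m))
  used <- rep(FALSE, n_vertices(m))
  marked <- 0L
  for (e in seq_len(n_edges(m))) {   # 120 vertex-disjoint singleton edges
    a <- m$edges[e, 1]; b <- m$edges[e, 2]
    if (!used[a] && !used[b]) {
      lab[e] <- "VESSEL"
      # block the whole 1-ring so the singleton stays a component
      nbr <- unique(as.vector(m$edges[m$edges[, 1] %in% c(a, b) |
                                        m$edges[, 2] %in% c(a, b), ]))
      used[nbr] <- TRUE
      marked <- marked + 1L
      if (marked >= 120L) break
    }
  }
  expect_error(split_segments(m, edge_labeling(lab, "edge", mesh = m)),
               "overflow")
})

test_that("part connections come from shared vertices with stored counts", {
  m <- fx_cyl_open()$mesh
  z1 <- m$vertices[m$edges[, 1], 3]; z2 <- m$vertices[m$edges[, 2], 3]
  # split exactly at a vertex ring: edges strictly below vs the rest
  lab <- ifelse(pmax(z1, z2) <= 10 + 1e-9, "VESSEL", "BIFURCATION")
  g <- build_part_graph(m, split_segments(m, edge_labeling(lab, "edge", mesh = m)))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$shared_vertices, 32L)  # one ring of 32 vertices
})

test_that("floating components warn and stay unconnected", {
  a <- fx_cyl_open()$mesh
  b_verts <- sweep(a$vertices, 2, c(50, 0, 0), `+`)
  m <- surface_mesh(rbind(a$vertices, b_verts),
                    rbind(a$triangles, a$triangles + nrow(a$vertices)),
                    merge_tolerance = 0)
  mid_x <- (m$vertices[m$edges[, 1], 1] + m$vertices[m$edges[, 2], 1]) / 2
  lab <- ifelse(mid_x < 25, "VESSEL", "INLET")
  expect_warning(g <- build_part_graph(m, split_segments(m, edge_labeling(lab, "edge", mesh = m))),
                 "disconnected")
  expect_equal(nrow(g$edges), 0L)
})

test_that("roles refine around the aneurysm and the refinement is idempotent", {
  tr <- fx_y_apex()
  g <- build_graph(tr$mesh, tr$ground_truth$face_labels)
  expect_equal(sum(g$nodes$role == "aneurysm"), 1L)
  expect_equal(sum(g$nodes$role == "aneurysm_bifurcation"), 1L)
  expect_equal(sum(g$nodes$role == "parent_vessel"), 3L)  # trunk + 2 daughters
  g2 <- assign_levels(refine_roles(g))
  expect_identical(g$nodes, g2$nodes)

  # without a collar the host touching the sac is an aneurysm vessel
  tr2 <- fx_sidewall()
  lab2 <- convert_labels(tr2$mesh, tr2$ground_truth$face_labels)
  relab <- ifelse(as.character(lab2$labels) == "BIFURCATION", "ANEURYSM",
                  as.character(lab2$labels))
  g3 <- refine_roles(build_part_graph(tr2$mesh,
                                      split_segments(tr2$mesh,
                                                     edge_labeling(relab, "edge", mesh = tr2$mesh))))
  expect_true("aneurysm_vessel" %in% g3$nodes$role)
  expect_false("aneurysm_bifurcation" %in% g3$nodes$role)
  # floor rule: 0 bifurcations on the path still means level 1
  g3 <- assign_levels(g3)
  expect_equal(g3$nodes$level[g3$nodes$role == "aneurysm_vessel"], 1L)
})

test_that("graphs without an aneurysm refuse role refinement with guidance", {
  tr <- fx_y_plain()
  lab <- convert_labels(tr$mesh, tr$ground_truth$face_labels)
  g <- build_part_graph(tr$mesh, split_segments(tr$mesh, lab))
  expect_error(refine_roles(g), "morphology-only")
})

test_that("levels count bifurcations on the path to the aneurysm", {
  tr <- fixture("seven_apex_tree", make_tree(synthetic_suite()$seven_apex))
  g <- build_graph(tr$mesh, tr$ground_truth$face_labels)
  lv <- g$nodes$level[g$nodes$class %in% c("VESSEL", "INLET")]
  expect_equal(sum(lv == 1, na.rm = TRUE), 3L)  # trunk + 2 first daughters
  expect_equal(sum(lv == 2, na.rm = TRUE), 4L)  # 4 second-tier daughters
  expect_equal(g$nodes$level[g$nodes$role == "aneurysm"], 0L)
})

test_that("level assignment is invariant under segment re-indexing", {
  tr <- fx_y_apex()
  lab <- convert_labels(tr$mesh, tr$ground_truth$face_labels)
  g1 <- assign_levels(refine_roles(build_part_graph(tr$mesh, split_segments(tr$mesh, lab))))
  perm <- rev(seq_len(nrow(g1$nodes)))
  g2 <- g1
  g2$nodes <- g1$nodes[perm, ]
  g2$segments <- g1$segments[perm]
  g2$edges$from <- match(g1$edges$from, perm)
  g2$edges$to <- match(g1$edges$to, perm)
  g2 <- assign_levels(refine_roles(g2))
  expect_equal(g2$nodes$level[order(g2$nodes$id)],
               g1$nodes$level[order(g1$nodes$id)])
})

test_that("the neck curve of an exact spherical cap is planar and true to size", {
  p <- fx_sac_patch()
  lab <- convert_labels(p$mesh, p$face_labels)
  g <- refine_roles(build_part_graph(p$mesh, split_segments(p$mesh, lab)))
  neck <- extract_neck_curve(p$mesh, lab, g)
  expect_lt(neck$planarity, 0.02)
  expect_lt(abs(2 * neck$equivalent_radius - 3.0) / 3.0, 0.10)

  expect_error(extract_neck_curve(p$mesh,
                                  edge_labeling(rep("VESSEL", n_edges(p$mesh)),
                                                "edge", mesh = p$mesh), g),
               "no ANEURYSM")
})

test_that("a generated side-wall sac recovers its construction neck radius", {
  tr <- fx_sidewall()  # generator neck radius 1.5 mm
  lab <- convert_labels(tr$mesh, tr$ground_truth$face_labels)
  g <- refine_roles(build_part_graph(tr$mesh, split_segments(tr$mesh, lab)))
  neck <- extract_neck_curve(tr$mesh, lab, g)
  expect_lt(abs(2 * neck$equivalent_radius - 3.0) / 3.0, 0.20)
})

test_that("segmentation scores match identity and brute-force set arithmetic", {
  m <- fx_cyl_open()$mesh
  set.seed(11)
  truth <- edge_labeling(sample(c("INLET", "ANEURYSM", "BIFURCATION", "VESSEL"),
                                n_edges(m), replace = TRUE), "edge", mesh = m)
  s_id <- segmentation_score(truth, truth)
  expect_equal(s_id$accuracy, 1.0)
  expect_true(all(s_id$per_class_iou == 1.0))

  # forced-count example: 10 edges of A, prediction half right
  t10 <- edge_labeling(rep("ANEURYSM", 10), "edge")
  p10 <- edge_labeling(c(rep("ANEURYSM", 5), rep("VESSEL", 5)), "edge")
  s10 <- segmentation_score(p10, t10)
  expect_equal(s10$accuracy, 0.5)
  expect_equal(unname(s10$per_class_iou[["ANEURYSM"]]), 0.5)
  expect_equal(unname(s10$per_class_iou[["VESSEL"]]), 0)   # present in pred only
  expect_true(is.na(s10$per_class_iou[["INLET"]]))         # absent from both

  pred <- edge_labeling(sample(c("INLET", "ANEURYSM", "BIFURCATION", "VESSEL"),
                               n_edges(m), replace = TRUE), "edge", mesh = m)
  s <- segmentation_score(pred, truth)
  p <- as.character(pred$labels); t <- as.character(truth$labels)
  for (cls in c("INLET", "ANEURYSM", "BIFURCATION", "VESSEL")) {
    inter <- length(intersect(which(p == cls), which(t == cls)))
    uni <- length(union(which(p == cls), which(t == cls)))
    expect_equal(unname(s$per_class_iou[[cls]]), inter / uni)
  }
  expect_equal(s$accuracy, mean(p == t))
})

test_that("geometric labelling separates sac from vessels on clean fixtures", {
  tr <- fx_sidewall()
  cp <- fx_case_pipeline("pipe_sidewall", tr, pitch = 0.35)
  hl <- heuristic_label(tr$mesh, cp$tree)
  sc <- segmentation_score(hl, convert_labels(tr$mesh, tr$ground_truth$face_labels))
  expect_gte(sc$accuracy, 0.90)

  # a bare Y-tree has no off-branch surface, hence no aneurysm edges
  cpy <- fx_case_pipeline("pipe_y_plain", fx_y_plain(), pitch = 0.4)
  hly <- heuristic_label(fx_y_plain()$mesh, cpy$tree)
  expect_equal(sum(hly$labels == "ANEURYSM"), 0L)

  # a single tube is entirely the inlet (sole and largest branch)
  fld <- fixture("field_cyl", medial_field(fx_cyl_capped()$mesh, pitch = 0.4))
  outl <- detect_closed_outlets(fx_cyl_capped()$mesh)
  tt <- compute_centerline_tree(fx_cyl_capped()$mesh, outl, field = fld)
  hlt <- heuristic_label(fx_cyl_capped()$mesh, tt)
  expect_true(all(hlt$labels == "INLET"))
})

test_that("graph exports include ids, classes, roles and levels", {
  tr <- fx_y_apex()
  g <- build_graph(tr$mesh, tr$ground_truth$face_labels)
  p <- tempfile(fileext = ".graphml")
  pj <- tempfile(fileext = ".json")
  write_vessel_graph(g, p, pj)
  gg <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::vcount(gg), nrow(g$nodes))
  expect_setequal(igraph::vertex_attr(gg, "numeric_id"), g$nodes$id)
  j <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(nrow(j$nodes), nrow(g$nodes))
})
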