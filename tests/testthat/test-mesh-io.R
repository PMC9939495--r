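test_that("a regular tetrahedron OFF file reads with the right combinatorics", {
  path <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 4 0",
               "1 1 1", "1 -1 -1", "-1 1 -1", "-1 -1 1",
               "3 0 1 2", "3 0 3 1", "3 0 2 3", "3 1 3 2"), path)
  m <- read_mesh(path)
  expect_equal(n_vertices(m), 4L)
  expect_equal(n_faces(m), 4L)
  expect_equal(n_edges(m), 6L)
  expect_true(validate_mesh(m)$is_watertight)
})

test_that("every edge of a closed tube has exactly two incident faces", {
  m <- fx_cyl_capped()$mesh
  expect_true(all(m$edge_face_count == 2L))
})

test_that("an open 32 x 50 swept cylinder has 1600 vertices and 64 boundary edges", {
  m <- fx_cyl_open()$mesh
  expect_equal(n_vertices(m), 1600L)
  vr <- validate_mesh(m)
  expect_false(vr$is_watertight)
  expect_equal(vr$boundary_edge_count, 64L)
})

test_that("deleting one triangle from a closed surface opens a 3-edge hole", {
  m0 <- fx_cyl_capped()$mesh
  m <- surface_mesh(m0$vertices, m0$triangles[-10, , drop = FALSE],
                    merge_tolerance = 0)
  vr <- validate_mesh(m)
  expect_false(vr$is_watertight)
  expect_equal(vr$boundary_edge_count, 3L)
})

test_that("meshes round-trip through every supported format", {
  m <- fx_cyl_open()$mesh
  for (fmt in c("obj", "off", "ply", "stl")) {
    for (binary in if (fmt %in% c("ply", "stl")) c(FALSE, TRUE) else FALSE) {
      path <- tempfile(fileext = paste0(".", fmt))
      write_mesh(m, path, binary = binary)
      m2 <- read_mesh(path)
      tol <- if (binary || fmt == "stl") 1e-5 else 1e-7  # float32 payloads
      expect_equal(n_faces(m2), n_faces(m), info = fmt)
      expect_lt(max(abs(m2$vertices[m2$triangles[, 1], ] -
                          m$vertices[m$triangles[, 1], ])), tol)
    }
  }
})

test_that("unreadable or unsupported files raise informative errors", {
  expect_error(read_mesh(tempfile(fileext = ".obj")), "does not exist")
  p <- tempfile(fileext = ".xyz")
  writeLines("junk", p)
  expect_error(read_mesh(p), "unsupported mesh format")
  p2 <- tempfile(fileext = ".off")
  writeLines(c("NOFF?", "1 1 1"), p2)
  expect_error(read_mesh(p2), "OFF")
})

test_that("face labels convert to edge labels with the transition-class tie-break", {
  m <- fx_cyl_open()$mesh
  allv <- edge_labeling(rep("VESSEL", n_faces(m)), "face", mesh = m)
  e <- convert_labels(m, allv)
  expect_true(all(e$labels == "VESSEL"))

  # two faces sharing an edge, ANEURYSM vs BIFURCATION -> BIFURCATION
  m2 <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                     rbind(c(1, 2, 3), c(2, 4, 3)), merge_tolerance = 0)
  lab2 <- convert_labels(m2, edge_labeling(c("ANEURYSM", "BIFURCATION"),
                                           "face", mesh = m2))
  shared <- which(m2$edge_face_count == 2L)
  expect_equal(as.character(lab2$labels[shared]), "BIFURCATION")

  # no class absent from the faces may appear on the edges
  tr <- fx_y_apex()
  eo <- convert_labels(tr$mesh, tr$ground_truth$face_labels)
  expect_true(all(unique(as.character(eo$labels)) %in%
                    unique(as.character(tr$ground_truth$face_labels$labels))))
})

test_that("face labels round-trip through segment splitting at ground-truth counts", {
  tr <- fx_y_apex()
  lab <- convert_labels(tr$mesh, tr$ground_truth$face_labels)
  segs <- split_segments(tr$mesh, lab)
  expect_equal(length(segs), nrow(tr$ground_truth$graph$nodes))
})

test_that("label sidecars round-trip in CSV and JSON", {
  tr <- fx_y_apex()
  lab <- tr$ground_truth$face_labels
  for (ext in c(".csv", ".json")) {
    p <- tempfile(fileext = ext)
    write_labels(lab, p)
    lab2 <- read_labels(p, mesh = tr$mesh)
    expect_equal(as.character(lab2$labels), as.character(lab$labels))
    expect_equal(lab2$element_kind, "face")
  }
})

test_that("label CSV index column starts at zero", {
  tr <- fx_y_apex()
  p <- tempfile(fileext = ".csv")
  write_labels(tr$ground_truth$face_labels, p)
  d <- read.csv(p)
  expect_equal(min(d$index), 0L)
  expect_equal(max(d$index), n_faces(tr$mesh) - 1L)
})

test_that("labels outside the four-class set are rejected", {
  expect_error(edge_labeling(c("VESSEL", "LUMEN"), "edge"), "class set")
  m <- fx_cyl_open()$mesh
  expect_error(edge_labeling(rep("VESSEL", 5), "face", mesh = m),
               "does not match")
})
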