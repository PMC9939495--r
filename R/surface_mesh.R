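#' Triangle surface mesh of a vascular model
#'
#' Container for a triangulated vessel surface in millimetres, with the
#' derived combinatorics every downstream stage relies on: a deduplicated,
#' lexicographically sorted edge list and the edge-to-face incidence.  The
#' edge ordering (each edge stored as `(min, max)` vertex pair, rows sorted
#' lexicographically) is part of the label sidecar file contract.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z) in mm.
#' @param triangles integer matrix, one row per triangle, 1-based vertex
#'   indices.
#' @param merge_tolerance vertices closer than this (mm) are merged; STL
#'   dialects duplicate vertices per facet, so merging is on by default.
#'
#' @return An object of class `surface_mesh`: a list with `vertices`,
#'   `triangles`, `edges` (e x 2), `edge_faces` (e x 2, `NA` where an edge
#'   has a single incident face), `edge_face_count`, and bookkeeping counts
#'   from construction (`duplicate_vertex_count`, `degenerate_triangle_count`).
#' @export
surface_mesh <- function(vertices, triangles, merge_tolerance = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3) stop("triangles must be an m x 3 matrix")
  if (nrow(vertices) == 0 || nrow(triangles) == 0) stop("empty mesh")
  if (min(triangles) < 1 || max(triangles) > nrow(vertices))
    stop("triangle refers to a vertex index outside 1..", nrow(vertices))

  dup_count <- 0L
  if (!is.null(merge_tolerance) && merge_tolerance > 0) {
    key <- paste(round(vertices[, 1] / merge_tolerance),
                 round(vertices[, 2] / merge_tolerance),
                 round(vertices[, 3] / merge_tolerance))
    first <- match(key, key)
    dup_count <- sum(first != seq_along(first))
    if (dup_count > 0) {
      keep <- which(first == seq_along(first))
      remap <- integer(nrow(vertices))
      remap[keep] <- seq_along(keep)
      remap <- remap[first]
      vertices <- vertices[keep, , drop = FALSE]
      triangles[] <- remap[triangles]
    }
  }

  degen <- triangles[, 1] == triangles[, 2] |
    triangles[, 2] == triangles[, 3] |
    triangles[, 1] == triangles[, 3]
  degen_count <- sum(degen)
  if (degen_count > 0) triangles <- triangles[!degen, , drop = FALSE]
  if (nrow(triangles) == 0) stop("mesh has no non-degenerate triangles")

  m <- nrow(triangles)
  he_a <- c(triangles[, 1], triangles[, 2], triangles[, 3])
  he_b <- c(triangles[, 2], triangles[, 3], triangles[, 1])
  a <- pmin(he_a, he_b)
  b <- pmax(he_a, he_b)
  key <- a * (nrow(vertices) + 1) + b
  ord <- order(a, b)
  ukeep <- ord[!duplicated(key[ord])]
  edges <- cbind(a[ukeep], b[ukeep])
  eid <- match(key, key[ukeep])

  face_of_he <- rep(seq_len(m), 3L)
  cnt <- tabulate(eid, nbins = nrow(edges))
  o <- order(eid)
  pos <- sequence(cnt)
  edge_faces <- matrix(NA_integer_, nrow(edges), 2)
  sel <- pos <= 2
  edge_faces[cbind(eid[o][sel], pos[sel])] <- face_of_he[o][sel]

  structure(list(
    vertices = vertices,
    triangles = triangles,
    edges = edges,
    edge_faces = edge_faces,
    edge_face_count = cnt,
    duplicate_vertex_count = dup_count,
    degenerate_triangle_count = degen_count
  ), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  vr <- validate_mesh(x)
  cat(sprintf(
    "<surface_mesh> %d vertices, %d triangles, %d edges (%s, %d boundary edges)\n",
    nrow(x$vertices), nrow(x$triangles), nrow(x$edges),
    if (vr$is_watertight) "watertight" else "open",
    vr$boundary_edge_count))
  invisible(x)
}

#' Mesh size accessors
#' @param mesh a [surface_mesh].
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$triangles)

#' @rdname n_vertices
#' @export
n_edges <- function(mesh) nrow(mesh$edges)

#' Face centroids of a mesh
#' @param mesh a [surface_mesh].
#' @return n_faces x 3 matrix.
#' @export
face_centroids <- function(mesh) {
  (mesh$vertices[mesh$triangles[, 1], , drop = FALSE] +
     mesh$vertices[mesh$triangles[, 2], , drop = FALSE] +
     mesh$vertices[mesh$triangles[, 3], , drop = FALSE]) / 3
}

face_normals <- function(mesh, normalize = TRUE) {
  v1 <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE] - v1
  e2 <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE] - v1
  n <- cross3m(e1, e2)
  if (normalize) n <- n / pmax(rownorms(n), .Machine$double.xmin)
  n
}

face_areas <- function(mesh) {
  v1 <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE] - v1
  e2 <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE] - v1
  rownorms(cross3m(e1, e2)) / 2
}

edge_midpoints <- function(mesh) {
  (mesh$vertices[mesh$edges[, 1], , drop = FALSE] +
     mesh$vertices[mesh$edges[, 2], , drop = FALSE]) / 2
}

#' Mesh sanity report
#'
#' Checks edge-manifoldness and watertightness and counts boundary edges,
#' merged duplicate vertices and dropped degenerate triangles.  A mesh is
#' watertight iff it is edge-manifold and has no boundary edges (edges with
#' exactly one incident triangle).
#'
#' @param mesh a [surface_mesh].
#' @return A list of class `mesh_validation` with fields `is_edge_manifold`,
#'   `is_watertight`, `boundary_edge_count`, `duplicate_vertex_count`,
#'   `degenerate_triangle_count`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  boundary <- sum(mesh$edge_face_count == 1L)
  manifold <- all(mesh$edge_face_count <= 2L)
  structure(list(
    is_edge_manifold = manifold,
    is_watertight = manifold && boundary == 0L,
    boundary_edge_count = boundary,
    duplicate_vertex_count = mesh$duplicate_vertex_count,
    degenerate_triangle_count = mesh$degenerate_triangle_count
  ), class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf(
    "<mesh_validation> edge-manifold: %s | watertight: %s | boundary edges: %d | merged duplicates: %d | degenerate dropped: %d\n",
    x$is_edge_manifold, x$is_watertight, x$boundary_edge_count,
    x$duplicate_vertex_count, x$degenerate_triangle_count))
  invisible(x)
}

#' Are points inside a closed surface?
#'
#' Vertical-ray crossing-parity test.
#' @param mesh a watertight [surface_mesh].
#' @param points 3D point or n x 3 matrix.
#' @return Logical vector.
#' @export
mesh_contains <- function(mesh, points) {
  points <- matrix(points, ncol = 3)
  points_inside(points, mesh$vertices, mesh$triangles)
}
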