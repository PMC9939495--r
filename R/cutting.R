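#' Local PCA frame at a seed vertex
#'
#' All mesh points within `neighborhood_radius` of the seed vertex enter a
#' principal component analysis: the dominant axis `pc1` approximates the
#' local vessel direction, the centroid the local centre, and the local
#' vessel diameter is approximated as twice the mean orthogonal distance of
#' the neighbourhood points to the axis line.
#'
#' @param mesh a [surface_mesh].
#' @param seed_vertex vertex index (1-based).
#' @param neighborhood_radius neighbourhood size in mm (default 3 mm).
#' @return An object of class `local_frame`: `center`, `axes` (3 x 3,
#'   columns pc1..pc3, orthonormal), `local_diameter`, `seed_vertex`,
#'   `neighborhood_radius`, and an `isotropic` warning flag set when the
#'   pc1/pc2 variance ratio is below 1.2 (no clear vessel direction).
#' @export
local_frame <- function(mesh, seed_vertex, neighborhood_radius = 3) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (seed_vertex < 1 || seed_vertex > n_vertices(mesh))
    stop("seed_vertex out of range")
  seed <- mesh$vertices[seed_vertex, ]
  d2 <- rowSums(sweep(mesh$vertices, 2, seed)^2)
  nb <- which(d2 <= neighborhood_radius^2)
  if (length(nb) < 10)
    stop("only ", length(nb),
         " mesh points in the neighborhood; increase neighborhood_radius")
  pts <- mesh$vertices[nb, , drop = FALSE]
  pc <- prcomp(pts, center = TRUE)
  axes <- pc$rotation
  # The local centre must lie on the vessel axis even when the
  # neighbourhood covers only part of the circumference (a surface patch
  # centroid would sit off-axis): fit a least-squares circle to the points
  # projected into the plane perpendicular to pc1.
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr)
  u <- as.vector(rel %*% axes[, 2]); v <- as.vector(rel %*% axes[, 3])
  fit <- tryCatch(qr.solve(cbind(u, v, 1), u^2 + v^2), error = function(e) c(0, 0, 0))
  if (vnorm(fit[1:2]) / 2 > neighborhood_radius) fit <- c(0, 0, 0)  # unstable fit
  ctr <- ctr + (fit[1] / 2) * axes[, 2] + (fit[2] / 2) * axes[, 3]
  rel <- sweep(pts, 2, ctr)
  along <- as.vector(rel %*% axes[, 1])
  ortho <- rownorms(rel - outer(along, axes[, 1]))
  iso <- (pc$sdev[1]^2) / (pc$sdev[2]^2) < 1.2
  if (iso)
    warning("isotropic neighborhood (pc1/pc2 variance ratio < 1.2); local direction is unreliable")
  structure(list(center = ctr, axes = axes,
                 local_diameter = 2 * mean(ortho),
                 seed_vertex = seed_vertex,
                 neighborhood_radius = neighborhood_radius,
                 isotropic = iso),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat(sprintf(
    "<local_frame> seed %d, r %.2f mm: center (%.2f, %.2f, %.2f), pc1 (%.3f, %.3f, %.3f), local diameter %.2f mm%s\n",
    x$seed_vertex, x$neighborhood_radius, x$center[1], x$center[2], x$center[3],
    x$axes[1, 1], x$axes[2, 1], x$axes[3, 1], x$local_diameter,
    if (x$isotropic) " [isotropic]" else ""))
  invisible(x)
}

# Intersection of the plane (center, normal) with the mesh: ordered loops of
# intersection points.  Returns list of loops, each with `points` (n x 3, on
# the plane) and `edge_ids` (the mesh edge each point lies on).
plane_cross_sections <- function(mesh, center, normal) {
  d <- as.vector(sweep(mesh$vertices, 2, center) %*% normal)
  eps <- 1e-9 * max(1, max(abs(d)))
  d[abs(d) <= eps] <- eps  # whole vertex rings can lie exactly on the plane
  ea <- mesh$edges[, 1]; eb <- mesh$edges[, 2]
  crossing <- which(d[ea] * d[eb] < 0)
  if (length(crossing) == 0) return(list())
  t <- d[ea[crossing]] / (d[ea[crossing]] - d[eb[crossing]])
  ipts <- mesh$vertices[ea[crossing], , drop = FALSE] +
    (mesh$vertices[eb[crossing], , drop = FALSE] -
       mesh$vertices[ea[crossing], , drop = FALSE]) * t
  # connect intersection points through the faces: each crossing triangle
  # has exactly two crossing edges
  eid_of <- integer(n_edges(mesh)); eid_of[crossing] <- seq_along(crossing)
  ef <- mesh$edge_faces[crossing, , drop = FALSE]
  face_pts <- split(rep(seq_along(crossing), 2), as.vector(ef))
  face_pts <- face_pts[!is.na(as.integer(names(face_pts)))]
  pairs <- do.call(rbind, lapply(face_pts, function(p)
    if (length(p) == 2) p else NULL))
  if (is.null(pairs)) return(list())
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(crossing) - igraph::vcount(g)))
  comp <- igraph::components(g)
  loops <- list()
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 3) next
    sub <- pairs[pairs[, 1] %in% members & pairs[, 2] %in% members, , drop = FALSE]
    cyc <- order_cycle(length(members), matrix(match(sub, members), ncol = 2))
    if (is.null(cyc)) next
    loops[[length(loops) + 1]] <-
      list(points = ipts[members[cyc], , drop = FALSE],
           edge_ids = crossing[members[cyc]])
  }
  loops
}

#' Cut a vessel end and extrude a perpendicular flow extension
#'
#' Cuts the mesh by the plane through the frame centre perpendicular to
#' `pc1`, discards the distal side (the side without aneurysm-labelled
#' elements when a labeling is supplied, otherwise the smaller surface-area
#' side), and extrudes the cut cross-section as a straight prism along
#' `pc1` by `extrusion_factor` times the local diameter.  The result is a
#' stitched, edge-manifold mesh whose new boundary loop is planar with
#' normal parallel to `pc1` — the perpendicular outlet hemodynamic solvers
#' need for developed flow profiles.
#'
#' @param mesh a [surface_mesh].
#' @param frame a [local_frame()].
#' @param extrusion_factor extension length in local diameters (default 5;
#'   0 performs a pure cut).
#' @param labeling optional edge [edge_labeling] used to keep the
#'   aneurysm-bearing side.
#' @return A [surface_mesh].
#' @export
cut_and_extrude <- function(mesh, frame, extrusion_factor = 5, labeling = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(frame, "local_frame"))
  if (extrusion_factor < 0) stop("extrusion_factor must be >= 0")
  pc1 <- frame$axes[, 1]
  loops <- plane_cross_sections(mesh, frame$center, pc1)
  if (length(loops) == 0) stop("cut plane misses the mesh")
  if (length(loops) > 1)
    stop("cut plane intersects the mesh in ", length(loops),
         " cross-section loops; move the seed away from a bifurcation")
  d <- as.vector(sweep(mesh$vertices, 2, frame$center) %*% pc1)

  # choose the side to keep
  fc_side <- sign(d[mesh$triangles[, 1]] + d[mesh$triangles[, 2]] +
                    d[mesh$triangles[, 3]])
  keep_positive <- NULL
  if (!is.null(labeling)) {
    lab <- if (labeling$element_kind == "edge") labeling else convert_labels(mesh, labeling)
    an <- which(as.character(lab$labels) == "ANEURYSM")
    if (length(an) > 0) {
      mid_d <- (d[mesh$edges[an, 1]] + d[mesh$edges[an, 2]]) / 2
      keep_positive <- mean(mid_d) > 0
    }
  }
  if (is.null(keep_positive)) {
    areas <- face_areas(mesh)
    keep_positive <- sum(areas[fc_side > 0]) >= sum(areas[fc_side < 0])
  }
  if (keep_positive) d <- -d  # retained side is always d < 0
  axis_out <- if (keep_positive) -pc1 else pc1  # from retained toward discarded

  eps <- 1e-9 * max(1, frame$local_diameter)
  d[abs(d) <= eps] <- eps  # nudge on-plane vertices to the discarded side
  vneg <- d < 0
  tr <- mesh$triangles
  tri_neg <- vneg[tr[, 1]] + vneg[tr[, 2]] + vneg[tr[, 3]]

  verts <- mesh$vertices
  new_tris <- list(tr[tri_neg == 3L, , drop = FALSE])
  # intersection vertex per crossing edge, shared between adjacent faces
  cross_edge <- which(d[mesh$edges[, 1]] * d[mesh$edges[, 2]] < 0)
  tpar <- d[mesh$edges[cross_edge, 1]] /
    (d[mesh$edges[cross_edge, 1]] - d[mesh$edges[cross_edge, 2]])
  ipts <- mesh$vertices[mesh$edges[cross_edge, 1], , drop = FALSE] +
    (mesh$vertices[mesh$edges[cross_edge, 2], , drop = FALSE] -
       mesh$vertices[mesh$edges[cross_edge, 1], , drop = FALSE]) * tpar
  iv_of_edge <- integer(n_edges(mesh))
  iv_of_edge[cross_edge] <- nrow(verts) + seq_along(cross_edge)
  verts <- rbind(verts, ipts)
  edge_lookup <- function(a, b) {
    key <- pmin(a, b) * (n_vertices(mesh) + 1) + pmax(a, b)
    ekey <- mesh$edges[, 1] * (n_vertices(mesh) + 1) + mesh$edges[, 2]
    iv_of_edge[match(key, ekey)]
  }
  mixed <- which(tri_neg %in% c(1L, 2L))
  for (fi in mixed) {
    v <- tr[fi, ]
    neg <- vneg[v]
    if (sum(neg) == 1L) {
      a <- v[neg]
      b <- v[(which(neg) %% 3) + 1]; cc <- v[((which(neg) + 1) %% 3) + 1]
      pab <- edge_lookup(a, b); pac <- edge_lookup(a, cc)
      if (is.na(pab) || pab == 0 || is.na(pac) || pac == 0) next
      new_tris[[length(new_tris) + 1]] <- matrix(c(a, pab, pac), 1, 3)
    } else if (sum(neg) == 2L) {
      c_pos <- v[!neg]
      ip <- which(!neg)
      a <- v[(ip %% 3) + 1]; b <- v[((ip + 1) %% 3) + 1]  # a, b negative, order a->b->c_pos
      pbc <- edge_lookup(b, c_pos); pca <- edge_lookup(c_pos, a)
      if (is.na(pbc) || pbc == 0 || is.na(pca) || pca == 0) next
      new_tris[[length(new_tris) + 1]] <- rbind(c(a, b, pbc), c(a, pbc, pca))
    }
  }
  tris <- do.call(rbind, new_tris)
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  tris[] <- remap[tris]
  cut_mesh <- surface_mesh(verts[used, , drop = FALSE], tris, merge_tolerance = 0)

  if (extrusion_factor > 0) {
    # the cut rim is the boundary loop lying in the cut plane
    rims <- find_boundary_loops(cut_mesh)
    in_plane <- vapply(rims, function(lp) {
      pd <- as.vector(sweep(cut_mesh$vertices[lp$vertex_cycle, , drop = FALSE],
                            2, frame$center) %*% pc1)
      max(abs(pd)) < 1e-6 * max(1, frame$local_diameter)
    }, TRUE)
    if (!any(in_plane)) stop("internal error: cut rim not found")
    rim <- rims[[which(in_plane)[1]]]$vertex_cycle
    shift <- extrusion_factor * frame$local_diameter
    ring <- cut_mesh$vertices[rim, , drop = FALSE] +
      matrix(axis_out * shift, length(rim), 3, byrow = TRUE)
    v2 <- rbind(cut_mesh$vertices, ring)
    rid <- nrow(cut_mesh$vertices) + seq_along(rim)
    nxt <- c(seq_along(rim)[-1], 1L)
    band <- rbind(cbind(rim, rim[nxt], rid[nxt]),
                  cbind(rim, rid[nxt], rid))
    cut_mesh <- surface_mesh(v2, rbind(cut_mesh$triangles, band),
                             merge_tolerance = 0)
  }
  cut_mesh
}
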