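#' Boundary loops of an open mesh
#'
#' Boundary edges are edges that belong to exactly one triangle; inlets and
#' outlets of an open vessel mesh are exactly the closed cycles these edges
#' form.  Each cycle is returned once, with a deterministic orientation
#' (starting at its smallest vertex index, proceeding toward the smaller
#' neighbour).
#'
#' @param mesh a [surface_mesh] (edge-manifold).
#' @return List of `boundary_loop` objects: `vertex_cycle` (ordered vertex
#'   indices) and `length` (closed polyline length, mm).
#' @export
find_boundary_loops <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (any(mesh$edge_face_count > 2))
    stop("mesh is not edge-manifold; boundary loops are undefined")
  bedges <- mesh$edges[mesh$edge_face_count == 1L, , drop = FALSE]
  if (nrow(bedges) == 0) return(list())
  vids <- sort(unique(as.vector(bedges)))
  deg <- tabulate(match(as.vector(bedges), vids), nbins = length(vids))
  if (any(deg != 2))
    stop("boundary edges do not close into simple cycles (non-manifold boundary)")
  le <- matrix(match(bedges, vids), ncol = 2)
  g <- igraph::graph_from_edgelist(le, directed = FALSE)
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(ci) {
    members <- which(comp$membership == ci)
    sub <- le[le[, 1] %in% members, , drop = FALSE]
    remap <- match(sub, members)
    cyc <- order_cycle(length(members), matrix(remap, ncol = 2))
    if (is.null(cyc)) stop("boundary component is not a simple cycle")
    cyc <- vids[members[cyc]]
    # deterministic orientation
    st <- which.min(cyc)
    cyc <- c(cyc[st:length(cyc)], cyc[seq_len(st - 1L)])
    prevv <- cyc[length(cyc)]; nxt <- cyc[2]
    if (prevv < nxt) cyc <- c(cyc[1], rev(cyc[-1]))
    pts <- mesh$vertices[cyc, , drop = FALSE]
    structure(list(vertex_cycle = cyc,
                   length = sum(rownorms(diff(rbind(pts, pts[1, , drop = FALSE]))))),
              class = "boundary_loop")
  })
}

#' Geometry of an opening
#'
#' Quantifies how circular and planar a vertex cycle is: `center` is the
#' vertex centroid, `normal` the smallest-variance principal axis,
#' `equivalent_radius` is `sqrt(enclosed planar area / pi)`, `planarity`
#' the maximum point-plane distance divided by the equivalent radius, and
#' `circularity` the coefficient of variation of the centre-to-vertex
#' distances (0 for a perfect circle).
#'
#' @param loop a `boundary_loop`, or an ordered n x 3 point matrix.
#' @param mesh the [surface_mesh] the loop indexes into (not needed when
#'   `loop` is a point matrix).
#' @param kind stored on the result (`"open-boundary"` or
#'   `"closed-detected"`).
#' @return An object of class `outlet`.
#' @export
outlet_geometry <- function(loop, mesh = NULL, kind = "open-boundary") {
  pts <- if (inherits(loop, "boundary_loop")) {
    stopifnot(!is.null(mesh))
    mesh$vertices[loop$vertex_cycle, , drop = FALSE]
  } else as.matrix(loop)
  if (nrow(pts) < 3) stop("an opening needs at least 3 vertices")
  pl <- fit_plane(pts)
  rel <- sweep(pts, 2, pl$center)
  sv <- svd(rel, nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("collinear opening vertices")
  inplane <- rel - outer(as.vector(rel %*% pl$normal), pl$normal)
  area <- polygon_area3(inplane)
  if (area <= 1e-12) stop("collinear opening vertices (zero enclosed area)")
  eq_r <- sqrt(area / pi)
  dists <- rownorms(rel)
  structure(list(
    center = pl$center,
    normal = pl$normal,
    equivalent_radius = eq_r,
    planarity = max(abs(rel %*% pl$normal)) / eq_r,
    circularity = sd(dists) / mean(dists),
    kind = kind,
    loop = if (inherits(loop, "boundary_loop")) loop else NULL,
    points = pts
  ), class = "outlet")
}

#' @export
print.outlet <- function(x, ...) {
  cat(sprintf(
    "<outlet %s> center (%.2f, %.2f, %.2f) mm, r_eq %.2f mm, planarity %.3f, circularity %.3f\n",
    x$kind, x$center[1], x$center[2], x$center[3],
    x$equivalent_radius, x$planarity, x$circularity))
  invisible(x)
}

#' Detect outlets on a closed (capped) mesh
#'
#' Flat caps on a tubular surface meet the wall at dihedral angles near 90
#' degrees.  Edges whose dihedral angle (between incident face normals,
#' 0 = coplanar; the crease angle is 180 minus the surface angle) falls
#' within `angle_tolerance` of 90 degrees are collected, their vertices
#' clustered into connected groups, and each group that orders into a
#' single cycle passing the circularity and planarity thresholds is
#' returned as an outlet.  The opening with the largest equivalent radius
#' is flagged `candidate_inlet` (the inlet vessel carries the enlarged
#' diameter).
#'
#' @param mesh a watertight [surface_mesh].
#' @param angle_tolerance half-width (degrees) of the accepted band around
#'   90 degrees.
#' @param circularity_threshold,planarity_threshold acceptance thresholds
#'   on the [outlet_geometry()] statistics.
#' @return List of `outlet` objects (possibly empty); each has a
#'   `candidate_inlet` flag.
#' @export
detect_closed_outlets <- function(mesh, angle_tolerance = 20,
                                  circularity_threshold = 0.15,
                                  planarity_threshold = 0.1) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nrm <- face_normals(mesh)
  ef <- mesh$edge_faces
  inner <- which(!is.na(ef[, 2]))
  cosang <- rowSums(nrm[ef[inner, 1], , drop = FALSE] *
                      nrm[ef[inner, 2], , drop = FALSE])
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  crease <- inner[abs(ang - 90) <= angle_tolerance]
  if (length(crease) == 0) return(list())
  ce <- mesh$edges[crease, , drop = FALSE]
  vids <- sort(unique(as.vector(ce)))
  le <- matrix(match(ce, vids), ncol = 2)
  g <- igraph::graph_from_edgelist(le, directed = FALSE)
  comp <- igraph::components(g)
  outlets <- list()
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 4) next
    sub <- le[le[, 1] %in% members & le[, 2] %in% members, , drop = FALSE]
    cyc <- order_cycle(length(members), matrix(match(sub, members), ncol = 2))
    if (is.null(cyc)) {
      # ring with chords (jagged crease): order by angle around the plane
      pts0 <- mesh$vertices[vids[members], , drop = FALSE]
      pl <- tryCatch(fit_plane(pts0), error = function(e) NULL)
      if (is.null(pl)) next
      relp <- sweep(pts0, 2, pl$center)
      e1 <- orthogonal_vector(pl$normal); e2 <- cross3(pl$normal, e1)
      cyc <- order(atan2(relp %*% e2, relp %*% e1))
    }
    pts <- mesh$vertices[vids[members[cyc]], , drop = FALSE]
    o <- tryCatch(outlet_geometry(pts, kind = "closed-detected"),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (o$circularity > circularity_threshold) next
    if (o$planarity > planarity_threshold) next
    o$vertex_cycle <- vids[members[cyc]]
    outlets[[length(outlets) + 1]] <- o
  }
  if (length(outlets) > 0) {
    # orient normals outward (away from the surface centroid) and flag the
    # largest opening as the candidate inlet
    ctr <- colMeans(mesh$vertices)
    radii <- vapply(outlets, `[[`, 0, "equivalent_radius")
    for (i in seq_along(outlets)) {
      if (sum(outlets[[i]]$normal * (outlets[[i]]$center - ctr)) < 0)
        outlets[[i]]$normal <- -outlets[[i]]$normal
      outlets[[i]]$candidate_inlet <- i == which.max(radii)
    }
  }
  outlets
}

#' Cap every boundary loop with a flat fan
#'
#' Adds one central vertex per boundary loop and fans triangles to the rim,
#' closing an open mesh so that interior-volume operations (inside tests,
#' inscribed spheres) are defined.
#'
#' @param mesh a [surface_mesh].
#' @param flatten project each rim onto its best-fit plane before capping,
#'   so the cap is genuinely flat (a jagged rim otherwise produces a
#'   crumpled cap whose dihedral angles are useless for outlet detection).
#' @return A watertight [surface_mesh] (when all openings were simple
#'   cycles).
#' @export
cap_boundary_loops <- function(mesh, flatten = TRUE) {
  loops <- find_boundary_loops(mesh)
  if (length(loops) == 0) return(mesh)
  verts <- mesh$vertices
  tris <- mesh$triangles
  for (lp in loops) {
    cyc <- lp$vertex_cycle
    pts <- verts[cyc, , drop = FALSE]
    if (flatten && nrow(pts) >= 3) {
      pl <- fit_plane(pts)
      off <- as.vector(sweep(pts, 2, pl$center) %*% pl$normal)
      verts[cyc, ] <- pts - outer(off, pl$normal)
    }
    ctr <- colMeans(verts[cyc, , drop = FALSE])
    verts <- rbind(verts, ctr)
    cid <- nrow(verts)
    nxt <- c(cyc[-1], cyc[1])
    tris <- rbind(tris, cbind(cyc, nxt, cid))
  }
  surface_mesh(verts, tris, merge_tolerance = 0)
}

#' Summarize outlets as a data frame / JSON
#'
#' @param outlets list of `outlet` objects.
#' @return data.frame with center, normal, equivalent radius and shape
#'   statistics, one row per opening.
#' @export
outlets_table <- function(outlets) {
  if (length(outlets) == 0)
    return(data.frame(cx = numeric(), cy = numeric(), cz = numeric(),
                      nx = numeric(), ny = numeric(), nz = numeric(),
                      equivalent_radius = numeric(), planarity = numeric(),
                      circularity = numeric(), kind = character()))
  do.call(rbind, lapply(outlets, function(o)
    data.frame(cx = o$center[1], cy = o$center[2], cz = o$center[3],
               nx = o$normal[1], ny = o$normal[2], nz = o$normal[3],
               equivalent_radius = o$equivalent_radius,
               planarity = o$planarity, circularity = o$circularity,
               kind = o$kind)))
}
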