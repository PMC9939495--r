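#' Interior maximal-inscribed-sphere field of a vessel surface
#'
#' Discretizes the interior of a closed vessel surface on a regular lattice.
#' Every kept site lies inside the surface (vertical-ray parity test) and
#' carries the radius of its maximal inscribed sphere, computed as the
#' distance to the nearest surface sample (mesh vertices plus face
#' centroids).  Sites are connected by 26-neighbour lattice adjacency; a
#' centerline is a shortest path on this graph with edge cost
#' length / mean endpoint radius, so paths stay where inscribed spheres are
#' large.  Open meshes are capped internally before the inside test.
#'
#' @param mesh a [surface_mesh].
#' @param pitch lattice spacing in mm; default scales with the mesh extent
#'   (bounding-box diagonal / 90, clamped to 0.25--0.6 mm).
#' @return An object of class `medial_field`: `sites` (n x 3), `radii`,
#'   `edges` (site-index pairs), `edge_length`, `samples` (the surface
#'   samples), `pitch`, and the capped mesh.
#' @export
medial_field <- function(mesh, pitch = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  vr <- validate_mesh(mesh)
  if (!vr$is_edge_manifold) stop("mesh is not edge-manifold")
  closed <- if (vr$is_watertight) mesh else cap_boundary_loops(mesh)
  ext <- apply(closed$vertices, 2, range)
  diag_len <- vnorm(ext[2, ] - ext[1, ])
  if (diag_len < 1e-9) stop("degenerate (flat) mesh")
  if (is.null(pitch)) pitch <- min(0.6, max(0.25, diag_len / 90))

  lo <- ext[1, ] - pitch
  dims <- as.integer(ceiling((ext[2, ] - ext[1, ]) / pitch)) + 3L
  ins <- grid_inside(closed$vertices, closed$triangles, lo, pitch, dims)
  dim(ins) <- dims
  if (!any(ins)) stop("no interior lattice sites found; is the surface closed and non-degenerate?")

  id <- array(0L, dims)
  id[ins] <- seq_len(sum(ins))
  idx <- which(ins, arr.ind = TRUE)
  sites <- cbind(lo[1] + (idx[, 1] - 1L) * pitch,
                 lo[2] + (idx[, 2] - 1L) * pitch,
                 lo[3] + (idx[, 3] - 1L) * pitch)

  samples <- surface_samples(closed, spacing = pitch)
  radii <- as.vector(RANN::nn2(samples, sites, k = 1)$nn.dists)

  # 26-neighbour adjacency via the 13 lexicographically positive offsets
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  e_from <- integer(0); e_to <- integer(0); e_len <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    xs <- seq_len(nx - abs(o[1])); ys <- seq_len(ny - abs(o[2])); zs <- seq_len(nz - abs(o[3]))
    a <- id[xs + max(0, -o[1]), ys + max(0, -o[2]), zs + max(0, -o[3]), drop = FALSE]
    b <- id[xs + max(0, o[1]), ys + max(0, o[2]), zs + max(0, o[3]), drop = FALSE]
    sel <- a > 0L & b > 0L
    if (any(sel)) {
      e_from <- c(e_from, a[sel]); e_to <- c(e_to, b[sel])
      e_len <- c(e_len, rep(pitch * sqrt(sum(o^2)), sum(sel)))
    }
  }
  structure(list(sites = sites, radii = radii,
                 edges = cbind(e_from, e_to), edge_length = e_len,
                 samples = samples, pitch = pitch, mesh = closed,
                 cache = new.env(parent = emptyenv())),
            class = "medial_field")
}

# Surface samples for distance queries: vertices, face centroids, and a
# barycentric lattice on any face larger than the target spacing (fan caps
# and other big triangles would otherwise be sampled too sparsely and
# inflate inscribed radii near them).
surface_samples <- function(mesh, spacing) {
  v1 <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  maxedge <- pmax(rownorms(v2 - v1), rownorms(v3 - v2), rownorms(v1 - v3))
  nsub <- pmin(8L, pmax(1L, as.integer(ceiling(maxedge / spacing))))
  out <- list(mesh$vertices, (v1 + v2 + v3) / 3)
  for (n in unique(nsub[nsub > 1])) {
    sel <- which(nsub == n)
    bar <- expand.grid(i = 0:n, j = 0:n)
    bar <- bar[bar$i + bar$j <= n & !(bar$i %in% c(0, n) & bar$j %in% c(0, n)), ]
    a <- bar$i / n; b <- bar$j / n; cc <- 1 - a - b
    for (r in seq_along(a))
      out[[length(out) + 1]] <- a[r] * v1[sel, , drop = FALSE] +
        b[r] * v2[sel, , drop = FALSE] + cc[r] * v3[sel, , drop = FALSE]
  }
  do.call(rbind, out)
}

#' @export
print.medial_field <- function(x, ...) {
  cat(sprintf("<medial_field> %d interior sites at pitch %.3g mm, radii %.2f-%.2f mm\n",
              nrow(x$sites), x$pitch, min(x$radii), max(x$radii)))
  invisible(x)
}

field_graph <- function(field) {
  if (is.null(field$cache$graph)) {
    w <- field$edge_length /
      ((field$radii[field$edges[, 1]] + field$radii[field$edges[, 2]]) / 2)
    g <- igraph::graph_from_edgelist(field$edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(field$sites) - igraph::vcount(g)))
    igraph::E(g)$weight <- w
    field$cache$graph <- g
  }
  field$cache$graph
}

snap_to_site <- function(field, point) {
  as.integer(RANN::nn2(field$sites, matrix(point, 1, 3), k = 1)$nn.idx)
}

# shortest path between two sites, as a site-index sequence
site_path <- function(field, from_site, to_site) {
  site_paths(field, from_site, to_site)[[1]]
}

# Shortest paths from one site to several targets, reconstructed from a
# single distance field with deterministic backward steps, so paths to
# different targets share their prefixes (one shortest-path tree).
site_paths <- function(field, from_site, to_sites) {
  g <- field_graph(field)
  dist <- suppressWarnings(igraph::distances(g, v = from_site))[1, ]
  n <- nrow(field$sites)
  if (is.null(field$cache$adj)) {
    w <- field$edge_length /
      ((field$radii[field$edges[, 1]] + field$radii[field$edges[, 2]]) / 2)
    ii <- c(field$edges[, 1], field$edges[, 2])
    jj <- c(field$edges[, 2], field$edges[, 1])
    ww <- c(w, w)
    ord <- order(ii)
    deg <- tabulate(ii, nbins = n)
    field$cache$adj <- list(ptr = c(0L, cumsum(deg)), nbr = jj[ord], w = ww[ord])
  }
  adj <- field$cache$adj
  lapply(to_sites, function(t) {
    if (!is.finite(dist[t])) return(integer(0))
    path <- t; cur <- t
    while (cur != from_site) {
      rng <- (adj$ptr[cur] + 1L):adj$ptr[cur + 1L]
      nb <- adj$nbr[rng]; wc <- adj$w[rng]
      ok <- which(abs(dist[nb] + wc - dist[cur]) <= 1e-9 * max(1, dist[cur]))
      if (length(ok) == 0) return(integer(0))
      # deterministic: smallest remaining distance, ties by site index
      cur <- nb[ok[order(dist[nb[ok]], nb[ok])[1]]]
      path <- c(cur, path)
      if (length(path) > n) return(integer(0))
    }
    path
  })
}

# Pull a lattice path onto the local cross-section centre: in the plane
# perpendicular to the running tangent, replace each point by the centroid
# of nearby surface samples within a thin slab, then refresh the inscribed
# radius.  Two passes suffice at lattice accuracy.
recenter_path <- function(field, pts, radii, iterations = 2) {
  n <- nrow(pts)
  if (n < 3) return(list(points = pts, radius = radii))
  slab <- 0.75 * field$pitch
  for (it in seq_len(iterations)) {
    tg <- rbind(pts[2, ] - pts[1, ], pts[3:n, ] - pts[1:(n - 2), ],
                pts[n, ] - pts[n - 1, ])
    tg <- tg / pmax(rownorms(tg), 1e-12)
    k <- min(nrow(field$samples), 2500L)
    nn <- RANN::nn2(field$samples, pts, k = k)
    for (i in seq_len(n)) {
      bound <- 1.4 * radii[i] + field$pitch
      cand <- nn$nn.idx[i, nn$nn.dists[i, ] < bound]
      if (length(cand) < 8) next
      rel <- sweep(field$samples[cand, , drop = FALSE], 2, pts[i, ])
      along <- as.vector(rel %*% tg[i, ])
      keep <- abs(along) < slab
      if (sum(keep) < 8) next
      # only recenter when the slab samples surround the point (a genuine
      # cross-section ring); oblique slices of caps or junction walls are
      # one-sided and would drag the point off-axis
      e1 <- orthogonal_vector(tg[i, ]); e2 <- cross3(tg[i, ], e1)
      u <- as.vector(rel[keep, , drop = FALSE] %*% e1)
      v <- as.vector(rel[keep, , drop = FALSE] %*% e2)
      ang <- sort(atan2(v, u))
      gaps <- c(diff(ang), 2 * pi - (ang[length(ang)] - ang[1]))
      if (max(gaps) > 1.8) next
      # least-squares circle centre of the ring (exact for a circle under
      # any angular sampling, unlike the raw centroid)
      A <- cbind(u, v, 1)
      fit <- tryCatch(qr.solve(A, u^2 + v^2), error = function(e) NULL)
      if (is.null(fit)) next
      delta <- (fit[1] / 2) * e1 + (fit[2] / 2) * e2
      dn <- vnorm(delta)
      if (dn > field$pitch) delta <- delta * (field$pitch / dn)  # guarded step
      pts[i, ] <- pts[i, ] + delta
    }
    radii <- as.vector(RANN::nn2(field$samples, pts, k = 1)$nn.dists)
  }
  list(points = pts, radius = radii)
}

new_centerline <- function(points, radius, source = NULL, target = NULL,
                           curvature = NULL, torsion = NULL) {
  structure(list(points = points,
                 arclength = polyline_arclength(points),
                 radius = radius,
                 curvature = curvature, torsion = torsion,
                 source = source, target = target),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  L <- x$arclength[length(x$arclength)]
  cat(sprintf("<centerline> %d points, length %.2f mm, radius %.2f-%.2f mm%s\n",
              nrow(x$points), L, min(x$radius), max(x$radius),
              if (!is.null(x$curvature))
                sprintf(", mean curvature %.4g mm^-1", mean(x$curvature)) else ""))
  invisible(x)
}

#' Centerline between two interior points
#'
#' Shortest path on the inscribed-sphere field with edge cost
#' length / mean endpoint radius, endpoints snapped to the nearest interior
#' site, followed by cross-section recentring.
#'
#' @param field a [medial_field()].
#' @param source,target 3D points (mm), inside the surface or on an outlet
#'   plane.
#' @param recenter pull the lattice path onto the cross-section centre.
#' @return A `centerline` (no curvature/torsion yet; see
#'   [frenet_geometry()]).
#' @export
compute_centerline <- function(field, source, target, recenter = TRUE) {
  stopifnot(inherits(field, "medial_field"))
  s <- snap_to_site(field, source)
  t <- snap_to_site(field, target)
  path <- site_path(field, s, t)
  if (length(path) < 2)
    stop("no interior path between the endpoints (disconnected sites near c(",
         paste(signif(target, 4), collapse = ", "), "))")
  pts <- field$sites[path, , drop = FALSE]
  rad <- field$radii[path]
  if (recenter) {
    rc <- recenter_path(field, pts, rad)
    pts <- rc$points; rad <- rc$radius
  }
  # terminate exactly at the requested seed points
  pts[1, ] <- source; pts[nrow(pts), ] <- target
  rad[c(1, length(rad))] <-
    as.vector(RANN::nn2(field$samples, pts[c(1, nrow(pts)), , drop = FALSE],
                        k = 1)$nn.dists)
  new_centerline(pts, rad, source = source, target = target)
}

#' Resample, smooth and attach Frenet curvature/torsion to a centerline
#'
#' The polyline is resampled to a uniform arc-length step, low-pass
#' smoothed with a centred moving average, and differentiated by central
#' finite differences: curvature `|r' x r''| / |r'|^3` and torsion
#' `(r' x r'') . r''' / |r' x r''|^2`.  Torsion is reported as 0 where the
#' curvature falls below `1e-4` mm^-1 (the Frenet frame is undefined on
#' straight runs).
#'
#' @param line a `centerline`.
#' @param resample_step target arc-length step in mm; default
#'   `min(0.1, length/100)`.
#' @param smoothing_window centred moving-average window (points; odd).
#' @return The `centerline` with uniform `arclength`, smoothed `points`,
#'   resampled `radius` and per-point `curvature`/`torsion`.
#' @export
frenet_geometry <- function(line, resample_step = NULL, smoothing_window = 5) {
  stopifnot(inherits(line, "centerline"))
  L <- line$arclength[length(line$arclength)]
  if (is.null(resample_step)) resample_step <- min(0.1, L / 100)
  n_out <- max(7L, as.integer(round(L / resample_step)) + 1L)
  if (nrow(line$points) < 3) stop("too few centerline points")
  rs <- resample_polyline(line$points, n_out = n_out)
  pts <- rs$points
  rad <- approx(line$arclength, line$radius, xout = rs$arclength,
                ties = "ordered", rule = 2)$y
  if (smoothing_window > 1) {
    w <- min(smoothing_window, nrow(pts) - (1 - nrow(pts) %% 2))
    if (w %% 2 == 0) w <- w - 1
    if (w >= 3) {
      half <- (w - 1) / 2
      sm <- pts
      kern <- rep(1 / w, w)
      for (dcol in 1:3) {
        padded <- c(rep(pts[1, dcol], half), pts[, dcol],
                    rep(pts[nrow(pts), dcol], half))
        sm[, dcol] <- stats::filter(padded, kern, sides = 2)[(half + 1):(half + nrow(pts))]
      }
      pts <- sm
    }
  }
  n <- nrow(pts)
  h <- rs$arclength[2] - rs$arclength[1]
  i <- 3:(n - 2)
  d1 <- (pts[i + 1, ] - pts[i - 1, ]) / (2 * h)
  d2 <- (pts[i + 1, ] - 2 * pts[i, ] + pts[i - 1, ]) / h^2
  d3 <- (pts[i + 2, ] - 2 * pts[i + 1, ] + 2 * pts[i - 1, ] - pts[i - 2, ]) / (2 * h^3)
  cr <- cross3m(d1, d2)
  crn <- rownorms(cr)
  kappa_i <- crn / pmax(rownorms(d1)^3, 1e-300)
  tau_i <- rowSums(cr * d3) / pmax(crn^2, 1e-300)
  tau_i[kappa_i < 1e-4] <- 0
  kappa <- c(kappa_i[1], kappa_i[1], kappa_i, kappa_i[length(i)], kappa_i[length(i)])
  tau <- c(tau_i[1], tau_i[1], tau_i, tau_i[length(i)], tau_i[length(i)])
  # the moving-average edge padding flattens the curve near the ends;
  # replace the affected values by the first fully smoothed interior one
  half <- if (smoothing_window > 1) (min(smoothing_window, n) - 1) %/% 2 else 0L
  pad <- min(2L + half, n %/% 2 - 1L)
  if (pad > 0 && n > 2 * (pad + 1)) {
    kappa[seq_len(pad)] <- kappa[pad + 1L]
    tau[seq_len(pad)] <- tau[pad + 1L]
    kappa[(n - pad + 1L):n] <- kappa[n - pad]
    tau[(n - pad + 1L):n] <- tau[n - pad]
  }
  out <- new_centerline(pts, rad, source = line$source, target = line$target,
                        curvature = kappa, torsion = tau)
  out$arclength <- polyline_arclength(pts)
  out
}

# Split (inlet -> outlet) paths at divergence points.  Lattice shortest
# paths to different outlets follow parallel equal-cost lanes rather than
# identical sites, so sharing is decided by proximity: paths are considered
# shared while every path in the group stays within a tolerance of the
# reference path (2.2 lattice cells, or half the local vessel radius).
split_paths_geometric <- function(paths, pitch) {
  branches <- list(); junctions <- list()
  recurse <- function(paths) {
    if (length(paths) == 1) {
      if (nrow(paths[[1]]$points) >= 2)
        branches[[length(branches) + 1]] <<- paths[[1]]
      return(invisible())
    }
    p1 <- paths[[1]]
    n1 <- nrow(p1$points)
    nearest <- lapply(paths[-1], function(p)
      RANN::nn2(p$points, p1$points, k = 1))
    tol <- pmax(2.2 * pitch, 0.5 * p1$radius)
    shared <- rep(TRUE, n1)
    for (nn in nearest) shared <- shared & nn$nn.dists[, 1] <= tol
    istar <- if (all(shared)) n1 else max(1L, which(!shared)[1] - 1L)
    if (istar >= 2)
      branches[[length(branches) + 1]] <<-
        list(points = p1$points[1:istar, , drop = FALSE],
             radius = p1$radius[1:istar])
    junctions[[length(junctions) + 1]] <<- p1$points[istar, ]
    tails <- vector("list", length(paths))
    tails[[1]] <- list(points = p1$points[istar:n1, , drop = FALSE],
                       radius = p1$radius[istar:n1])
    for (k in seq_along(nearest)) {
      cut <- nearest[[k]]$nn.idx[istar, 1]
      p <- paths[[k + 1]]
      tails[[k + 1]] <- list(points = p$points[cut:nrow(p$points), , drop = FALSE],
                             radius = p$radius[cut:length(p$radius)])
    }
    tails <- tails[vapply(tails, function(p) nrow(p$points) >= 2, TRUE)]
    if (length(tails) == 0) return(invisible())
    # group tails that continue together: single linkage on a probe point
    # a few steps past the junction
    probe <- do.call(rbind, lapply(tails, function(p)
      p$points[min(6L, nrow(p$points)), ]))
    gid <- seq_len(nrow(probe))
    dmat <- as.matrix(dist(probe))
    for (a in seq_len(nrow(probe)))
      for (b in seq_len(nrow(probe)))
        if (dmat[a, b] <= 2.5 * pitch) gid[gid == gid[b]] <- gid[a]
    groups <- split(tails, gid)
    if (length(groups) == 1 && length(tails) == length(paths) && istar == 1) {
      for (p in tails) recurse(list(p))  # cannot separate further; emit as-is
    } else if (length(groups) == 1) {
      for (p in groups[[1]]) recurse(list(p))
    } else {
      for (grp in groups) recurse(grp)
    }
  }
  recurse(paths)
  list(branches = branches,
       junction_points = do.call(rbind, junctions) %||% matrix(0, 0, 3))
}

#' Per-segment centerline tree from automatically detected outlets
#'
#' Computes one centerline per (inlet, outlet) pair on the inscribed-sphere
#' field, splits the paths at shared-prefix divergence points into
#' branches, recentres each branch, and assigns every branch to the
#' semantic-graph segment containing the majority of its points.
#'
#' @param mesh a [surface_mesh].
#' @param outlets list of `outlet` objects (>= 2); the candidate inlet (or
#'   the largest opening) seeds all paths.
#' @param graph optional `vessel_graph` for segment assignment.
#' @param field optional precomputed [medial_field()].
#' @param pitch lattice pitch forwarded to [medial_field()].
#' @return An object of class `centerline_tree`: `branches` (list of
#'   `centerline`), `junction_points`, `segment_assignment` (graph node id
#'   per branch, `NA` without a graph), `inlet_outlet` index.
#' @export
compute_centerline_tree <- function(mesh, outlets, graph = NULL, field = NULL,
                                    pitch = NULL) {
  if (length(outlets) < 2) stop("need at least 2 outlets")
  if (is.null(field)) field <- medial_field(mesh, pitch = pitch)
  radii <- vapply(outlets, `[[`, 0, "equivalent_radius")
  inlet_flag <- vapply(outlets, function(o) isTRUE(o$candidate_inlet), TRUE)
  inlet <- if (any(inlet_flag)) which(inlet_flag)[1] else which.max(radii)
  src_site <- snap_to_site(field, outlets[[inlet]]$center)
  others <- setdiff(seq_along(outlets), inlet)
  tgt_sites <- vapply(others, function(i) snap_to_site(field, outlets[[i]]$center), 0L)
  raw <- site_paths(field, src_site, tgt_sites)
  paths <- list(); reached <- integer(0)
  for (j in seq_along(others)) {
    if (length(raw[[j]]) < 2) {
      warning("outlet ", others[j], " unreachable from the inlet; omitted")
      next
    }
    paths[[length(paths) + 1]] <- raw[[j]]
    reached <- c(reached, others[j])
  }
  if (length(paths) == 0) stop("fewer than 2 outlets are connected through the interior")
  pp <- lapply(seq_along(paths), function(j) {
    pts <- field$sites[paths[[j]], , drop = FALSE]
    pts[1, ] <- outlets[[inlet]]$center            # seed exactly at openings
    pts[nrow(pts), ] <- outlets[[reached[j]]]$center
    list(points = pts, radius = field$radii[paths[[j]]])
  })
  sp <- split_paths_geometric(pp, field$pitch)
  branches <- lapply(sp$branches, function(br) {
    rc <- recenter_path(field, br$points, br$radius)
    new_centerline(rc$points, rc$radius)
  })
  junctions <- sp$junction_points

  assignment <- rep(NA_integer_, length(branches))
  if (!is.null(graph)) {
    vmap <- vertex_segment_map(graph, n_vertices(field$mesh))
    for (b in seq_along(branches)) {
      nnv <- RANN::nn2(field$mesh$vertices, branches[[b]]$points, k = 1)$nn.idx
      segs <- vmap[as.vector(nnv)]
      segs <- segs[!is.na(segs)]
      if (length(segs) > 0)
        assignment[b] <- as.integer(names(sort(table(segs), decreasing = TRUE))[1])
    }
  }
  # the branch that starts at the inlet opening is the root (trunk)
  src <- outlets[[inlet]]$center
  starts <- vapply(branches, function(b)
    vnorm(b$points[1, ] - src), 0)
  structure(list(branches = branches, junction_points = junctions,
                 segment_assignment = assignment,
                 inlet_outlet = inlet, outlet_index = reached,
                 root_branch = which.min(starts),
                 field = field),
            class = "centerline_tree")
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat(sprintf("<centerline_tree> %d branches, %d junctions\n",
              length(x$branches), nrow(x$junction_points)))
  invisible(x)
}

#' Assign centerline-tree branches to semantic graph segments
#'
#' Each branch goes to the graph node whose segment contains the majority
#' of the branch points (by nearest mesh vertex).
#'
#' @param tree a `centerline_tree`.
#' @param graph a `vessel_graph`.
#' @return The tree with `segment_assignment` filled in.
#' @export
assign_tree_segments <- function(tree, graph) {
  vmap <- vertex_segment_map(graph, n_vertices(tree$field$mesh))
  for (b in seq_along(tree$branches)) {
    nnv <- RANN::nn2(tree$field$mesh$vertices, tree$branches[[b]]$points, k = 1)$nn.idx
    segs <- vmap[as.vector(nnv)]
    segs <- segs[!is.na(segs)]
    if (length(segs) > 0)
      tree$segment_assignment[b] <-
        as.integer(names(sort(table(segs), decreasing = TRUE))[1])
  }
  tree
}

#' Apply [frenet_geometry()] to every branch of a centerline tree
#'
#' @param tree a `centerline_tree`.
#' @param ... forwarded to [frenet_geometry()].
#' @return The tree with curvature/torsion-bearing branches.
#' @export
tree_frenet <- function(tree, ...) {
  tree$branches <- lapply(tree$branches, frenet_geometry, ...)
  tree
}
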