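#' Branch specification for synthetic vessel trees
#'
#' A branch is a space curve (straight line, circular arc, or circular
#' helix) swept with a radius profile.  Arcs and helices have constant
#' analytic curvature/torsion (helix with radius `r` and pitch parameter
#' `c`: curvature `r/(r^2+c^2)`, torsion `c/(r^2+c^2)`), which makes every
#' branch its own Frenet oracle.
#'
#' @param kind `"line"`, `"arc"` or `"helix"`.
#' @param length arc length of the branch (mm).
#' @param radius constant radius (mm), or length-2 vector `c(r0, r1)` for a
#'   linear taper.
#' @param curvature arc curvature (mm^-1), for `kind = "arc"`.
#' @param helix_radius,helix_pitch helix parameters `r` and `c` (mm), for
#'   `kind = "helix"`.
#' @param bulge optional localized Gaussian bulge of the radius profile:
#'   `list(amplitude, position, width)` (mm, arc-length mm, mm).
#' @param parent index of the parent branch (children attach at the parent
#'   end), or `NA` for the root.
#' @param angle tilt (degrees) of the branch start tangent away from the
#'   parent end tangent.
#' @param azimuth rotation (degrees) of the tilt plane around the parent
#'   end tangent.
#' @return A list of class `branch_spec`.
#' @export
branch_spec <- function(kind = c("line", "arc", "helix"), length,
                        radius = 2, curvature = 0.1,
                        helix_radius = 2, helix_pitch = 1,
                        bulge = NULL, parent = NA_integer_,
                        angle = 40, azimuth = 0) {
  kind <- match.arg(kind)
  stopifnot(length > 0, all(radius > 0))
  if (kind == "arc") stopifnot(curvature > 0)
  if (!is.null(bulge)) stopifnot(all(c("amplitude", "position", "width") %in% names(bulge)))
  structure(list(kind = kind, length = length, radius = radius,
                 curvature = curvature, helix_radius = helix_radius,
                 helix_pitch = helix_pitch, bulge = bulge,
                 parent = as.integer(parent), angle = angle, azimuth = azimuth),
            class = "branch_spec")
}

# radius profile r(s) of a branch
branch_radius <- function(branch, s) {
  r <- if (length(branch$radius) == 2) {
    branch$radius[1] + (branch$radius[2] - branch$radius[1]) * s / branch$length
  } else rep(branch$radius[1], length(s))
  if (!is.null(branch$bulge)) {
    b <- branch$bulge
    r <- r + b$amplitude * exp(-0.5 * ((s - b$position) / b$width)^2)
  }
  if (any(r <= 0)) stop("radius profile not positive everywhere")
  r
}

branch_kappa_tau <- function(branch) {
  switch(branch$kind,
    line = c(0, 0),
    arc = c(branch$curvature, 0),
    helix = {
      r <- branch$helix_radius; cc <- branch$helix_pitch
      c(r, cc) / (r^2 + cc^2)
    })
}

# Evaluate a placed branch curve at arc lengths s: points, unit tangents,
# Frenet normals (transport normal for lines) and the analytic kappa/tau.
curve_eval <- function(branch, s) {
  P0 <- branch$origin; T0 <- branch$frame$t; N0 <- branch$frame$n
  n <- length(s)
  kt <- branch_kappa_tau(branch)
  if (branch$kind == "line") {
    P <- matrix(P0, n, 3, byrow = TRUE) + outer(s, T0)
    Tt <- matrix(T0, n, 3, byrow = TRUE)
    Nn <- matrix(N0, n, 3, byrow = TRUE)
  } else if (branch$kind == "arc") {
    R <- 1 / branch$curvature
    a <- s / R
    P <- matrix(P0, n, 3, byrow = TRUE) +
      outer(R * sin(a), T0) + outer(R * (1 - cos(a)), N0)
    Tt <- outer(cos(a), T0) + outer(sin(a), N0)
    Nn <- outer(-sin(a), T0) + outer(cos(a), N0)
  } else {
    r <- branch$helix_radius; cc <- branch$helix_pitch
    L2 <- sqrt(r^2 + cc^2)
    t <- s / L2
    u0 <- c(0, r, cc) / L2          # canonical tangent at t = 0
    n0 <- c(-1, 0, 0)               # canonical Frenet normal at t = 0
    b0 <- cross3(u0, n0)
    B0 <- cross3(T0, N0)
    Rm <- cbind(T0, N0, B0) %*% t(cbind(u0, n0, b0))
    Cc <- cbind(r * cos(t) - r, r * sin(t), cc * t)
    Cd <- cbind(-r * sin(t), r * cos(t), rep(cc, n)) / L2
    Cn <- cbind(-cos(t), -sin(t), rep(0, n))
    P <- matrix(P0, n, 3, byrow = TRUE) + Cc %*% t(Rm)
    Tt <- Cd %*% t(Rm)
    Nn <- Cn %*% t(Rm)
  }
  list(points = P, tangent = Tt, normal = Nn,
       kappa = rep(kt[1], n), tau = rep(kt[2], n))
}

# Place branches of a tree: root at the origin along +z, children at the
# parent end, tilted by (angle, azimuth) from the parent end frame.
place_branches <- function(branches) {
  for (i in seq_along(branches)) {
    br <- branches[[i]]
    if (is.na(br$parent)) {
      br$origin <- c(0, 0, 0)
      br$frame <- list(t = c(0, 0, 1), n = c(1, 0, 0))
    } else {
      if (br$parent >= i) stop("branches must be listed parents-first")
      par <- branches[[br$parent]]
      ev <- curve_eval(par, par$length)
      Te <- unitize(ev$tangent[1, ]); Ne <- unitize(ev$normal[1, ])
      Ne <- unitize(Ne - sum(Ne * Te) * Te)
      Be <- cross3(Te, Ne)
      a <- br$angle * pi / 180; ph <- br$azimuth * pi / 180
      d <- cos(ph) * Ne + sin(ph) * Be
      T0 <- unitize(cos(a) * Te + sin(a) * d)
      N0 <- unitize(-sin(a) * Te + cos(a) * d)
      br$origin <- ev$points[1, ]
      br$frame <- list(t = T0, n = N0)
    }
    branches[[i]] <- br
  }
  branches
}

#' Swept-tube mesh for a single branch
#'
#' Sweeps a circle of the branch radius profile along the branch curve with
#' a rotation-minimizing (parallel-transport) frame.  Optionally caps the
#' ends with flat fans perpendicular to the end tangents.
#'
#' @param branch a [branch_spec()] (placed at the origin along +z).
#' @param n_circ circumferential samples (>= 8).
#' @param n_axial axial samples (>= 4).
#' @param capped cap the two ends with flat planar fans.
#' @return `list(mesh, ground_truth)`: the [surface_mesh] and a ground
#'   truth holding the analytic centerline (points, arclength, radius,
#'   curvature, torsion).
#' @export
make_tube <- function(branch, n_circ = 32, n_axial = 50, capped = FALSE) {
  stopifnot(inherits(branch, "branch_spec"), n_circ >= 8, n_axial >= 4)
  branch$origin <- branch$origin %||% c(0, 0, 0)
  branch$frame <- branch$frame %||% list(t = c(0, 0, 1), n = c(1, 0, 0))
  s <- seq(0, branch$length, length.out = n_axial)
  r <- branch_radius(branch, s)
  ev <- curve_eval(branch, s)
  bad <- which(ev$kappa * r >= 1)
  if (length(bad) > 0)
    stop(sprintf("self-intersecting sweep: radius %.3g exceeds radius of curvature at arc length %.3g mm",
                 r[bad[1]], s[bad[1]]))
  # parallel-transport frame to avoid torsion-induced twist of the sweep
  N <- matrix(0, n_axial, 3)
  N[1, ] <- unitize(ev$normal[1, ] - sum(ev$normal[1, ] * ev$tangent[1, ]) * ev$tangent[1, ])
  for (i in 2:n_axial) {
    v <- N[i - 1, ] - sum(N[i - 1, ] * ev$tangent[i, ]) * ev$tangent[i, ]
    N[i, ] <- unitize(v)
  }
  B <- cross3m(ev$tangent, N)
  th <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  verts <- matrix(0, n_axial * n_circ, 3)
  for (i in seq_len(n_axial)) {
    ring <- matrix(ev$points[i, ], n_circ, 3, byrow = TRUE) +
      r[i] * (outer(cos(th), N[i, ]) + outer(sin(th), B[i, ]))
    verts[(i - 1) * n_circ + seq_len(n_circ), ] <- ring
  }
  tris <- vector("list", n_axial - 1)
  for (i in seq_len(n_axial - 1)) {
    a <- (i - 1) * n_circ + seq_len(n_circ)
    b <- a %% (n_circ) + (i - 1) * n_circ + 1L  # next around the ring
    a2 <- a + n_circ; b2 <- b + n_circ
    tris[[i]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  tris <- do.call(rbind, tris)
  if (capped) {
    c1 <- nrow(verts) + 1L; c2 <- nrow(verts) + 2L
    verts <- rbind(verts, ev$points[1, ], ev$points[n_axial, ])
    ring1 <- seq_len(n_circ)
    ringN <- (n_axial - 1) * n_circ + seq_len(n_circ)
    nxt <- c(seq_len(n_circ)[-1], 1L)
    tris <- rbind(tris,
                  cbind(ring1[nxt], ring1, c1),
                  cbind(ringN, ringN[nxt], c2))
  }
  mesh <- surface_mesh(verts, tris, merge_tolerance = 0)
  gt <- structure(list(
    centerlines = list(list(points = ev$points, arclength = s, radius = r,
                            curvature = ev$kappa, torsion = ev$tau)),
    branches = list(branch)), class = "vessel_ground_truth")
  list(mesh = mesh, ground_truth = gt)
}

#' Tree specification for the implicit synthetic generator
#'
#' @param branches list of [branch_spec()]; parents must precede children.
#' @param inlet_branch index of the inlet (root) branch.
#' @param aneurysm optional sac: `list(branch, position, sac_radius,
#'   offset, azimuth, bleb)`.  `position` is the arc-length fraction of the
#'   host branch (1 places the sac at the branch end / bifurcation apex);
#'   `offset` is the distance from the host centerline to the sac center in
#'   mm (defaults to host radius + 0.6 * sac radius); `bleb` is an optional
#'   `list(radius, azimuth)` blister on the dome.
#' @param blend_distance smooth-union blending length (mm); also the width
#'   of the bifurcation/collar transition zones in the ground-truth labels.
#' @param voxel_pitch marching sampling pitch (mm); must be at most the
#'   minimum branch radius / 4.
#' @return A list of class `tree_spec`.
#' @export
tree_spec <- function(branches, inlet_branch = 1L, aneurysm = NULL,
                      blend_distance = 0.9, voxel_pitch = 0.4) {
  stopifnot(length(branches) >= 1,
            all(vapply(branches, inherits, TRUE, "branch_spec")))
  if (inlet_branch < 1 || inlet_branch > length(branches))
    stop("inlet_branch out of range")
  if (!is.null(aneurysm)) {
    stopifnot(all(c("branch", "position", "sac_radius") %in% names(aneurysm)))
    if (aneurysm$branch < 1 || aneurysm$branch > length(branches))
      stop("aneurysm host branch out of range")
    if (aneurysm$position < 0 || aneurysm$position > 1)
      stop("aneurysm host position must lie within the branch domain [0, 1]")
  }
  structure(list(branches = branches, inlet_branch = as.integer(inlet_branch),
                 aneurysm = aneurysm, blend_distance = blend_distance,
                 voxel_pitch = voxel_pitch),
            class = "tree_spec")
}

# exact log-sum-exp smooth minimum, accumulated pairwise
smooth_min <- function(a, b, k) {
  m <- pmin(a, b)
  m - k * log1p(exp(-abs(a - b) / k))
}

#' Generate a watertight labelled vessel tree
#'
#' Builds a signed-distance field as the smooth-minimum union of swept-tube
#' (capsule-chain) distances per branch plus sac/bleb spheres, extracts the
#' zero level set by marching tetrahedra, and emits complete ground truth:
#' per-face class labels (`ANEURYSM` where the nearest primitive is the
#' sac/bleb; `BIFURCATION` where two primitives are within
#' `blend_distance` of each other — junction zones and the sac collar;
#' `INLET` on the inlet branch; `VESSEL` elsewhere), per-face segment ids,
#' the expected semantic graph with roles and levels derived from the
#' branch topology, and analytic per-branch centerlines.
#'
#' @param spec a [tree_spec()].
#' @return `list(mesh, ground_truth)`.
#' @export
make_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  branches <- place_branches(spec$branches)
  nb <- length(branches)
  min_r <- min(vapply(branches, function(b) min(b$radius), 0))
  if (spec$voxel_pitch > min_r / 4)
    stop(sprintf("pitch too coarse: voxel_pitch %.3g > min radius / 4 = %.3g",
                 spec$voxel_pitch, min_r / 4))

  # capsule chains per branch (chord error ~ step^2 * curvature / 8,
  # far below the marching pitch)
  step <- spec$voxel_pitch
  chains <- lapply(branches, function(b) {
    s <- seq(0, b$length, length.out = max(8L, ceiling(b$length / step) + 1L))
    ev <- curve_eval(b, s)
    r <- branch_radius(b, s)
    kap <- branch_kappa_tau(b)[1]
    if (any(kap * r >= 1))
      stop(sprintf("self-intersecting sweep: radius exceeds radius of curvature (branch curvature %.3g)", kap))
    list(s = s, points = ev$points, radius = r,
         curvature = ev$kappa, torsion = ev$tau)
  })

  spheres <- sac_primitives(branches, spec$aneurysm)

  # bounding grid
  allp <- do.call(rbind, lapply(chains, `[[`, "points"))
  maxr <- max(vapply(seq_len(nb), function(i) max(chains[[i]]$radius), 0))
  pad <- maxr + spec$blend_distance + 2 * spec$voxel_pitch
  lo <- apply(allp, 2, min) - pad
  hi <- apply(allp, 2, max) + pad
  if (!is.null(spheres)) {
    for (sp in spheres) {
      lo <- pmin(lo, sp$center - sp$radius - spec$blend_distance - 2 * spec$voxel_pitch)
      hi <- pmax(hi, sp$center + sp$radius + spec$blend_distance + 2 * spec$voxel_pitch)
    }
  }
  h <- spec$voxel_pitch
  dims <- pmax(8L, as.integer(ceiling((hi - lo) / h)) + 2L)
  gx <- lo[1] + h * (seq_len(dims[1]) - 1)
  gy <- lo[2] + h * (seq_len(dims[2]) - 1)
  gz <- lo[3] + h * (seq_len(dims[3]) - 1)
  grid <- cbind(rep(gx, times = dims[2] * dims[3]),
                rep(rep(gy, each = dims[1]), times = dims[3]),
                rep(gz, each = dims[1] * dims[2]))

  k <- spec$blend_distance / 4  # union smoothing; collar width is gap-based
  f <- rep(Inf, nrow(grid))
  for (ch in chains) {
    d <- chain_distance(grid, ch)
    f <- smooth_min(f, d, k)
  }
  if (!is.null(spheres)) {
    for (sp in spheres) {
      d <- rownorms(sweep(grid, 2, sp$center)) - sp$radius
      f <- smooth_min(f, d, k)
    }
  }
  f[abs(f) < 1e-9] <- -1e-9
  iso <- march_tetrahedra(f, dims, lo, h)
  if (nrow(iso$vertices) == 0) stop("empty isosurface; check the tree spec")
  # merge above the file round-trip tolerance so written/re-read meshes
  # keep their vertex and face counts (the marching clamp can emit vertex
  # pairs closer than any print precision)
  mesh <- surface_mesh(iso$vertices, iso$triangles, merge_tolerance = 2e-6)
  vr <- validate_mesh(mesh)
  if (!vr$is_watertight)
    stop("generated surface is not watertight; decrease voxel_pitch")
  comp <- igraph::components(igraph::graph_from_edgelist(mesh$edges, directed = FALSE))
  if (comp$no > 1)
    stop("disconnected field components (", comp$no, "); branches do not form one connected tree")

  gt <- tree_ground_truth(mesh, branches, chains, spheres, spec)
  list(mesh = mesh, ground_truth = gt)
}

# sac + bleb spheres for a tree spec; also records host/neck geometry
sac_primitives <- function(branches, an) {
  if (is.null(an)) return(NULL)
  host <- branches[[an$branch]]
  s_host <- an$position * host$length
  ev <- curve_eval(host, s_host)
  r_host <- branch_radius(host, s_host)
  offset <- an$offset %||% (r_host + 0.6 * an$sac_radius)
  dir <- if (an$position >= 1 - 1e-9) {
    ev$tangent[1, ]                       # apex sac continues the parent axis
  } else {
    ph <- (an$azimuth %||% 0) * pi / 180
    Ne <- unitize(ev$normal[1, ] - sum(ev$normal[1, ] * ev$tangent[1, ]) * ev$tangent[1, ])
    Be <- cross3(ev$tangent[1, ], Ne)
    cos(ph) * Ne + sin(ph) * Be
  }
  center <- ev$points[1, ] + offset * unitize(dir)
  out <- list(list(center = center, radius = an$sac_radius, what = "sac",
                   host_branch = an$branch, host_s = s_host,
                   host_point = ev$points[1, ], host_radius = r_host,
                   dome_dir = unitize(dir)))
  if (!is.null(an$bleb)) {
    bph <- (an$bleb$azimuth %||% 45) * pi / 180
    axis1 <- orthogonal_vector(dir)
    bdir <- unitize(cos(bph) * unitize(dir) + sin(bph) * axis1)
    bc <- center + (an$sac_radius + 0.45 * an$bleb$radius) * bdir
    out[[2]] <- list(center = bc, radius = an$bleb$radius, what = "bleb")
  }
  out
}

# Absorb tiny same-label face islands into their surrounding label; keeps
# the ground truth free of one-face slivers at transition-zone boundaries.
clean_face_labels <- function(mesh, labels, min_faces = 12L, max_passes = 5L) {
  ef <- mesh$edge_faces
  inner <- which(!is.na(ef[, 2]))
  for (pass in seq_len(max_passes)) {
    same <- inner[labels[ef[inner, 1]] == labels[ef[inner, 2]]]
    g <- igraph::graph_from_edgelist(ef[same, , drop = FALSE], directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(labels) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_along(labels)]
    sizes <- tabulate(comp)
    small <- which(sizes < min_faces)
    if (length(small) == 0) return(labels)
    for (ci in small) {
      members <- which(comp == ci)
      nbr <- c(ef[inner, 2][ef[inner, 1] %in% members],
               ef[inner, 1][ef[inner, 2] %in% members])
      nbr <- setdiff(nbr, members)
      if (length(nbr) == 0) next
      labels[members] <- names(sort(table(labels[nbr]), decreasing = TRUE))[1]
    }
  }
  labels
}

chain_distance <- function(points, chain) {
  np <- nrow(chain$points)
  capsule_field(points,
                chain$points[-np, , drop = FALSE],
                chain$points[-1, , drop = FALSE],
                chain$radius[-np], chain$radius[-1])$distance
}

# ground-truth labels, segments, expected graph, centerlines
tree_ground_truth <- function(mesh, branches, chains, spheres, spec) {
  nb <- length(branches)
  ctr <- face_centroids(mesh)
  D <- matrix(Inf, nrow(ctr), nb + 1L)
  for (i in seq_len(nb)) D[, i] <- chain_distance(ctr, chains[[i]])
  if (!is.null(spheres)) {
    dan <- rep(Inf, nrow(ctr))
    for (sp in spheres) dan <- pmin(dan, rownorms(sweep(ctr, 2, sp$center)) - sp$radius)
    D[, nb + 1L] <- dan
  }
  ord1 <- max.col(-D)                      # nearest primitive
  d1 <- D[cbind(seq_len(nrow(D)), ord1)]
  D2 <- D; D2[cbind(seq_len(nrow(D)), ord1)] <- Inf
  d2 <- apply(D2, 1, min)
  gap <- d2 - d1
  labels <- ifelse(ord1 == nb + 1L, "ANEURYSM",
                   ifelse(ord1 == spec$inlet_branch, "INLET", "VESSEL"))
  # transition collar: faces close to a second primitive.  Sac-nearest
  # faces always stay ANEURYSM so the sac/collar interface coincides with
  # the geometric sac-host intersection (the ostium).
  labels[gap < spec$blend_distance & ord1 != nb + 1L] <- "BIFURCATION"
  labels <- clean_face_labels(mesh, labels)
  face_labels <- edge_labeling(labels, "face", mesh = mesh)

  graph <- expected_graph_from_labels(mesh, labels)
  segment_ids <- graph$face_component

  structure(list(
    face_labels = face_labels,
    segment_ids = segment_ids,
    graph = graph,
    centerlines = chains,
    branches = branches,
    inlet_branch = spec$inlet_branch,
    sac = if (!is.null(spheres)) spheres[[1]] else NULL,
    neck_radius = if (!is.null(spheres)) {
      sp <- spheres[[1]]
      dd <- vnorm(sp$center - sp$host_point) - sp$host_radius
      if (abs(dd) < sp$radius) sqrt(sp$radius^2 - dd^2) else NA_real_
    } else NA_real_,
    blend_distance = spec$blend_distance,
    voxel_pitch = spec$voxel_pitch
  ), class = "vessel_ground_truth")
}

#' Expected semantic graph by brute-force label-component enumeration
#'
#' The generator's oracle for the semantic-graph stage: connected
#' components of same-label faces are found with a plain union-find over
#' face adjacencies, component connections are enumerated vertex by vertex
#' (different labels meeting at a vertex connect their components), roles
#' are refined by the stated rules, and levels are counted with a
#' hand-rolled breadth-first search.  Deliberately independent of the
#' edge-based/igraph machinery the pipeline itself uses.
#'
#' @param mesh a [surface_mesh].
#' @param face_labels character vector or face [edge_labeling].
#' @return `list(nodes, edges)`: `nodes` is a data.frame with `class`,
#'   `role`, `level`; `edges` an index-pair matrix.
#' @export
expected_graph_from_labels <- function(mesh, face_labels) {
  if (inherits(face_labels, "edge_labeling")) {
    stopifnot(face_labels$element_kind == "face")
    face_labels <- as.character(face_labels$labels)
  }
  nf <- n_faces(mesh)
  stopifnot(length(face_labels) == nf)
  parent <- seq_len(nf)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ef <- mesh$edge_faces
  for (r in which(!is.na(ef[, 2]))) {
    a <- ef[r, 1]; b <- ef[r, 2]
    if (face_labels[a] == face_labels[b]) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_len(nf), find, 0L)
  comp_ids <- sort(unique(root))
  comp <- match(root, comp_ids)
  nc <- length(comp_ids)
  nodes <- data.frame(class = face_labels[comp_ids],
                      role = tolower(face_labels[comp_ids]),
                      level = NA_integer_, stringsAsFactors = FALSE)
  nodes$size <- tabulate(comp, nbins = nc)

  # vertex-wise enumeration of component contacts
  vface <- cbind(as.vector(mesh$triangles), rep(seq_len(nf), 3))
  o <- order(vface[, 1])
  vv <- vface[o, 1]; cc <- comp[vface[o, 2]]
  edges <- matrix(integer(), 0, 2)
  seen <- character(0)
  brk <- c(which(diff(vv) > 0), length(vv))
  st <- 1L
  for (en in brk) {
    cs <- unique(cc[st:en])
    if (length(cs) > 1) {
      for (a in seq_len(length(cs) - 1))
        for (b in (a + 1):length(cs)) {
          key <- paste0(min(cs[a], cs[b]), "_", max(cs[a], cs[b]))
          if (!(key %in% seen)) {
            seen <- c(seen, key)
            edges <- rbind(edges, c(min(cs[a], cs[b]), max(cs[a], cs[b])))
          }
        }
    }
    st <- en + 1L
  }

  adj <- lapply(seq_len(nc), function(i)
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
  an_all <- which(nodes$class == "ANEURYSM")
  if (length(an_all) > 0) {
    an <- an_all[which.max(nodes$size[an_all])]
    if (length(an_all) > 1) nodes$role[setdiff(an_all, an)] <- "aneurysm_secondary"
    for (v in adj[[an]]) {
      if (nodes$class[v] == "BIFURCATION") nodes$role[v] <- "aneurysm_bifurcation"
      if (nodes$class[v] %in% c("VESSEL", "INLET")) nodes$role[v] <- "aneurysm_vessel"
    }
    for (b in which(nodes$role == "aneurysm_bifurcation"))
      for (v in adj[[b]])
        if (nodes$class[v] %in% c("VESSEL", "INLET")) nodes$role[v] <- "parent_vessel"
    # breadth-first levels: count bifurcation components on the path
    dist <- rep(NA_integer_, nc); dist[an] <- 0L
    queue <- an
    ord <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      ord <- c(ord, v)
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    nbif <- rep(NA_integer_, nc); nbif[an] <- 0L
    for (v in ord[-1]) {
      pred <- adj[[v]][which.min(dist[adj[[v]]])]
      nbif[v] <- nbif[pred] + (nodes$class[v] == "BIFURCATION")
    }
    nodes$level[an] <- 0L
    vl <- nodes$class %in% c("VESSEL", "INLET") & !is.na(nbif)
    nodes$level[vl] <- pmax(1L, nbif[vl])
  }
  nodes$size <- NULL
  list(nodes = nodes, edges = edges, face_component = comp)
}

#' Synthetic cohort of aneurysm-bearing vessel trees
#'
#' Generates `n` Y-shaped trees (inlet trunk plus two daughter branches,
#' apex sac at the bifurcation), with branch curvature and torsion drawn
#' from log-normal baselines shifted by `effect`, emulating a clinical
#' cohort at a fixed seed.  Branches are helices so every case carries
#' closed-form curvature/torsion ground truth.
#'
#' @param n number of cases.
#' @param seed master seed; case `i` uses a derived sub-seed, so any case
#'   is reproducible in isolation.
#' @param effect additive offsets `list(curvature, torsion)` (mm^-1) applied
#'   to every drawn branch value.
#' @param voxel_pitch marching pitch passed to the per-case [tree_spec()].
#' @return List of `n` elements, each `list(mesh, ground_truth)`.
#' @export
make_cohort <- function(n, seed, effect = list(curvature = 0, torsion = 0),
                        voxel_pitch = 0.45) {
  stopifnot(n >= 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((as.integer(seed) * 7919L + i * 104729L) %% 2147483647L)
    kap <- rlnorm(3, log(0.08), 0.4) + (effect$curvature %||% 0)
    tau <- rlnorm(3, log(0.04), 0.5) + (effect$torsion %||% 0)
    hr <- kap / (kap^2 + tau^2)
    hc <- tau / (kap^2 + tau^2)
    r_d <- runif(2, 1.8, 2.2)
    r_t <- 1.35 * max(r_d)
    len <- runif(3, 11, 14)
    az <- runif(1, 0, 360)
    trunk <- branch_spec("helix", length = len[1], radius = r_t,
                         helix_radius = hr[1], helix_pitch = hc[1])
    d1 <- branch_spec("helix", length = len[2], radius = r_d[1],
                      helix_radius = hr[2], helix_pitch = hc[2],
                      parent = 1L, angle = runif(1, 38, 52), azimuth = az)
    d2 <- branch_spec("helix", length = len[3], radius = r_d[2],
                      helix_radius = hr[3], helix_pitch = hc[3],
                      parent = 1L, angle = runif(1, 38, 52), azimuth = az + 180)
    spec <- tree_spec(list(trunk, d1, d2), inlet_branch = 1L,
                      aneurysm = list(branch = 1L, position = 1,
                                      sac_radius = runif(1, 2.4, 3.0)),
                      blend_distance = 0.9, voxel_pitch = voxel_pitch)
    out[[i]] <- make_tree(spec)
  }
  out
}

#' Bundled fixture suite of vessel-tree specifications
#'
#' A fixed set of tree specifications spanning the topologies the package
#' is validated on: 1 to 7 branches, apex and side-wall sacs, with and
#' without blebs.  Together with [make_cohort()] cases these form the
#' synthetic validation suite.
#'
#' @return Named list of [tree_spec()] objects.
#' @export
synthetic_suite <- function() {
  y_branches <- function(r_trunk = 2.6, r_d = c(2, 2), kap = 0.05, ang = 45)
    list(branch_spec("line", length = 12, radius = r_trunk),
         branch_spec("arc", length = 12, radius = r_d[1], curvature = kap,
                     parent = 1L, angle = ang, azimuth = 0),
         branch_spec("arc", length = 12, radius = r_d[2], curvature = kap,
                     parent = 1L, angle = ang, azimuth = 180))
  seven <- c(y_branches(2.8, c(2.2, 2.2), 0.04, 42),
             list(branch_spec("line", length = 9, radius = 1.7, parent = 2L,
                              angle = 40, azimuth = 60),
                  branch_spec("line", length = 9, radius = 1.7, parent = 2L,
                              angle = 40, azimuth = 240),
                  branch_spec("line", length = 9, radius = 1.7, parent = 3L,
                              angle = 40, azimuth = 120),
                  branch_spec("line", length = 9, radius = 1.7, parent = 3L,
                              angle = 40, azimuth = 300)))
  list(
    single_plain = tree_spec(
      list(branch_spec("line", length = 15, radius = 2)), voxel_pitch = 0.4),
    single_sidewall = tree_spec(
      list(branch_spec("line", length = 16, radius = 1.8)),
      aneurysm = list(branch = 1, position = 0.5, sac_radius = 2.8,
                      azimuth = 0),
      blend_distance = 0.8, voxel_pitch = 0.4),
    single_sidewall_bleb = tree_spec(
      list(branch_spec("line", length = 16, radius = 1.8)),
      aneurysm = list(branch = 1, position = 0.5, sac_radius = 2.8,
                      azimuth = 0, bleb = list(radius = 1.1, azimuth = 40)),
      blend_distance = 0.8, voxel_pitch = 0.4),
    helix_sidewall = tree_spec(
      list(branch_spec("helix", length = 16, radius = 1.8,
                       helix_radius = 6, helix_pitch = 3)),
      aneurysm = list(branch = 1, position = 0.5, sac_radius = 2.6,
                      azimuth = 90),
      blend_distance = 0.8, voxel_pitch = 0.4),
    y_apex = tree_spec(
      y_branches(), aneurysm = list(branch = 1, position = 1, sac_radius = 2.8),
      blend_distance = 0.9, voxel_pitch = 0.4),
    y_apex_bleb = tree_spec(
      y_branches(), aneurysm = list(branch = 1, position = 1, sac_radius = 2.8,
                                    bleb = list(radius = 1.2, azimuth = 30)),
      blend_distance = 0.9, voxel_pitch = 0.4),
    y_daughter_sidewall = tree_spec(
      y_branches(2.6, c(2.1, 1.9), 0.04, 48),
      aneurysm = list(branch = 2, position = 0.55, sac_radius = 2.4,
                      azimuth = 90),
      blend_distance = 0.9, voxel_pitch = 0.4),
    y_plain = tree_spec(y_branches(), blend_distance = 0.9, voxel_pitch = 0.4),
    five_apex = tree_spec(
      c(y_branches(2.8, c(2.2, 2.0), 0.04, 42),
        list(branch_spec("line", length = 9, radius = 1.7, parent = 2L,
                         angle = 40, azimuth = 60),
             branch_spec("line", length = 9, radius = 1.7, parent = 2L,
                         angle = 40, azimuth = 240))),
      aneurysm = list(branch = 1, position = 1, sac_radius = 3.0),
      blend_distance = 0.9, voxel_pitch = 0.4),
    seven_apex = tree_spec(
      seven, aneurysm = list(branch = 1, position = 1, sac_radius = 3.0),
      blend_distance = 0.9, voxel_pitch = 0.4),
    seven_trunk_sidewall = tree_spec(
      seven, aneurysm = list(branch = 1, position = 0.45, sac_radius = 2.6,
                             azimuth = 90),
      blend_distance = 0.9, voxel_pitch = 0.4))
}

#' Do a semantic graph and an expected graph agree?
#'
#' Exact comparison used by the validation suite: the node multisets of
#' (class, role, level) must be identical and the graphs class-preserving
#' isomorphic (VF2 with node colors built from class/role/level).
#'
#' @param graph a `vessel_graph` from the pipeline.
#' @param expected `list(nodes, edges)` from the generator ground truth.
#' @return TRUE/FALSE.
#' @export
graphs_match <- function(graph, expected) {
  a <- graph$nodes[, c("class", "role", "level")]
  b <- expected$nodes[, c("class", "role", "level")]
  key <- function(d) sort(paste(d$class, d$role, ifelse(is.na(d$level), -1, d$level)))
  if (!identical(key(a), key(b))) return(FALSE)
  mk <- function(edges, n) {
    g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
    igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  }
  ga <- mk(graph$edges[, c("from", "to")], nrow(a))
  gb <- mk(expected$edges, nrow(b))
  lv <- sort(unique(c(key(a), key(b))))
  col <- function(d) as.integer(factor(
    paste(d$class, d$role, ifelse(is.na(d$level), -1, d$level)), levels = lv))
  igraph::isomorphic(ga, gb, method = "vf2",
                     vertex.color1 = col(a), vertex.color2 = col(b))
}

#' Write a generated case to disk in the package file contracts
#'
#' Emits the mesh (format from the mesh path extension), the face labels as
#' a CSV sidecar, the expected graph as GraphML and the analytic
#' centerlines as `branch_id,s,x,y,z,radius` CSV.
#'
#' @param case a `list(mesh, ground_truth)` from [make_tree()].
#' @param dir output directory (created if missing).
#' @param basename file stem.
#' @return Named vector of written paths, invisibly.
#' @export
write_ground_truth <- function(case, dir, basename = "tree") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- case$ground_truth
  paths <- c(mesh = file.path(dir, paste0(basename, ".obj")),
             labels = file.path(dir, paste0(basename, "_labels.csv")),
             graph = file.path(dir, paste0(basename, "_graph.graphml")),
             centerlines = file.path(dir, paste0(basename, "_centerlines.csv")))
  write_mesh(case$mesh, paths[["mesh"]])
  write_labels(gt$face_labels, paths[["labels"]])
  g <- igraph::graph_from_edgelist(gt$graph$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(gt$graph$nodes) - igraph::vcount(g)))
  igraph::V(g)$class <- gt$graph$nodes$class
  igraph::V(g)$role <- gt$graph$nodes$role
  igraph::V(g)$level <- ifelse(is.na(gt$graph$nodes$level), -1L, gt$graph$nodes$level)
  igraph::write_graph(g, paths[["graph"]], format = "graphml")
  cl <- do.call(rbind, lapply(seq_along(gt$centerlines), function(i) {
    ch <- gt$centerlines[[i]]
    data.frame(branch_id = i, s = ch$s %||% ch$arclength,
               x = ch$points[, 1], y = ch$points[, 2], z = ch$points[, 3],
               radius = ch$radius)
  }))
  write.csv(cl, paths[["centerlines"]], row.names = FALSE)
  invisible(paths)
}

#' Spherical sac on a flat host patch (exact morphometry fixture)
#'
#' Builds an exactly triangulated spherical cap of radius `sac_radius`
#' whose intersection with the host plane is a circle of radius
#' `neck_radius`, attached to a flat annular host patch, with face labels
#' (`ANEURYSM` on the sphere, a one-ring `BIFURCATION` collar on the
#' patch, `VESSEL` outside).  Because nothing is blended or sampled on a
#' lattice, the neck circle, cap height and widths have closed forms:
#' height `= R + sqrt(R^2 - r^2)`, neck diameter `= 2 r`.
#'
#' @param sac_radius sphere radius R (mm).
#' @param neck_radius neck circle radius r < R (mm).
#' @param patch_radius outer radius of the annular host patch.
#' @param n_circ circumferential resolution.
#' @param n_lat latitudinal rings on the cap.
#' @return `list(mesh, face_labels, height, neck_diameter)`.
#' @export
make_sac_patch <- function(sac_radius = 3, neck_radius = 1.5,
                           patch_radius = 6, n_circ = 64, n_lat = 40) {
  stopifnot(neck_radius < sac_radius)
  d <- sqrt(sac_radius^2 - neck_radius^2)
  cz <- d                      # sphere centre height; plane at z = 0
  th0 <- acos(-d / sac_radius) # polar angle of the neck circle (from +z)
  th <- seq(0, th0, length.out = n_lat + 1)[-1]
  ph <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  verts <- rbind(c(0, 0, cz + sac_radius))
  for (t in th)
    verts <- rbind(verts, cbind(sac_radius * sin(t) * cos(ph),
                                sac_radius * sin(t) * sin(ph),
                                cz + sac_radius * cos(t)))
  ring_id <- function(i) 1L + (i - 1L) * n_circ + seq_len(n_circ)  # i-th ring
  tris <- list(); labels <- character(0)
  apexs <- ring_id(1)
  nxt <- c(seq_len(n_circ)[-1], 1L)
  tris[[1]] <- cbind(1L, apexs, apexs[nxt])
  labels <- c(labels, rep("ANEURYSM", n_circ))
  for (i in seq_len(length(th) - 1)) {
    a <- ring_id(i); b <- ring_id(i + 1)
    tris[[length(tris) + 1]] <- rbind(cbind(a, b, b[nxt]), cbind(a, b[nxt], a[nxt]))
    labels <- c(labels, rep("ANEURYSM", 2 * n_circ))
  }
  # annular patch rings on z = 0 (first ring of faces is the collar)
  rr <- c(seq(neck_radius, neck_radius + 1.2, length.out = 4)[-1],
          seq(neck_radius + 1.6, patch_radius, length.out = 8))
  inner <- ring_id(length(th))  # the neck circle vertices (z = 0)
  prev <- inner
  for (j in seq_along(rr)) {
    newv <- cbind(rr[j] * cos(ph), rr[j] * sin(ph), 0)
    base <- nrow(verts)
    verts <- rbind(verts, newv)
    cur <- base + seq_len(n_circ)
    tris[[length(tris) + 1]] <- rbind(cbind(prev, cur[nxt], cur),
                                      cbind(prev, prev[nxt], cur[nxt]))
    labels <- c(labels, rep(if (j <= 2) "BIFURCATION" else "VESSEL", 2 * n_circ))
    prev <- cur
  }
  mesh <- surface_mesh(verts, do.call(rbind, tris), merge_tolerance = 1e-9)
  list(mesh = mesh,
       face_labels = edge_labeling(labels, "face", mesh = mesh),
       height = sac_radius + d,
       neck_diameter = 2 * neck_radius)
}

#' Open the terminal ends of a generated tree
#'
#' Cuts every terminal branch (the inlet root end and all leaf ends) by a
#' plane perpendicular to the local branch tangent, a short way inside the
#' rounded implicit end cap, leaving one clean planar boundary rim per
#' terminal — the open-mesh situation in which outlets are found from
#' boundary edges.  Falls back to deleting the cap faces if a plane cut is
#' not possible at some terminal.
#'
#' @param case `list(mesh, ground_truth)` from [make_tree()].
#' @param inset how far inside the end point the cut plane sits, in units
#'   of the local radius.
#' @return `list(mesh, ground_truth, terminals)` where `terminals` is a
#'   data.frame of the opened end centers, outward normals and radii.
#' @export
open_tree_ends <- function(case, inset = 0.25) {
  gt <- case$ground_truth
  mesh <- case$mesh
  term <- terminal_ends(gt)
  for (i in seq_len(nrow(term))) {
    e <- as.numeric(term[i, c("x", "y", "z")])
    nrm <- unitize(as.numeric(term[i, c("nx", "ny", "nz")]))
    ctr <- e - inset * term$radius[i] * nrm
    frame <- structure(list(
      center = ctr,
      axes = cbind(nrm, orthogonal_vector(nrm),
                   cross3(nrm, orthogonal_vector(nrm))),
      local_diameter = 2 * term$radius[i],
      seed_vertex = NA_integer_, neighborhood_radius = NA_real_,
      isotropic = FALSE), class = "local_frame")
    cut <- tryCatch(cut_and_extrude(mesh, frame, extrusion_factor = 0),
                    error = function(e) NULL)
    n_before <- length(find_boundary_loops(mesh))
    if (!is.null(cut) &&
        length(find_boundary_loops(cut)) == n_before + 1L) {
      mesh <- cut
      term[i, c("x", "y", "z")] <- as.list(ctr)
    } else {
      mesh <- drop_cap_faces(mesh, e, nrm, term$radius[i])
    }
  }
  # carry the class labels over to the opened mesh (cut faces take the
  # label of the nearest original face)
  lab_open <- NULL
  if (!is.null(gt$face_labels)) {
    nn <- RANN::nn2(face_centroids(case$mesh), face_centroids(mesh), k = 1)
    lab_open <- edge_labeling(
      as.character(gt$face_labels$labels)[as.vector(nn$nn.idx)],
      "face", mesh = mesh)
  }
  list(mesh = mesh, ground_truth = gt, terminals = term,
       face_labels = lab_open)
}

# fallback opening: delete faces beyond the end plane and peel pinched rims
drop_cap_faces <- function(mesh, e, nrm, radius, margin = 0.15) {
  ctr <- face_centroids(mesh)
  d <- as.matrix(sweep(ctr, 2, e)) %*% nrm
  near <- rownorms(sweep(ctr, 2, e)) < 2.5 * radius
  tris <- mesh$triangles[!(near & d > margin * radius), , drop = FALSE]
  for (pass in 1:10) {
    m2 <- surface_mesh(mesh$vertices, tris, merge_tolerance = 0)
    be <- m2$edges[m2$edge_face_count == 1L, , drop = FALSE]
    deg <- tabulate(as.vector(be), nbins = nrow(m2$vertices))
    bad <- which(deg > 2)
    if (length(bad) == 0) break
    touch <- tris[, 1] %in% bad | tris[, 2] %in% bad | tris[, 3] %in% bad
    tris <- tris[!touch, , drop = FALSE]
  }
  surface_mesh(mesh$vertices, tris, merge_tolerance = 0)
}

# terminal end planes of a generated tree: root start + leaf ends
terminal_ends <- function(gt) {
  branches <- gt$branches
  nb <- length(branches)
  has_child <- vapply(seq_len(nb), function(i)
    any(vapply(branches, function(b) identical(b$parent, i), TRUE)), TRUE)
  apex_host <- if (!is.null(gt$sac)) gt$sac$host_branch else NA_integer_
  apex_at_end <- !is.null(gt$sac) &&
    abs(gt$sac$host_s - branches[[gt$sac$host_branch]]$length) < 1e-9
  rows <- list()
  for (i in seq_len(nb)) {
    ch <- gt$centerlines[[i]]
    np <- nrow(ch$points)
    if (is.na(branches[[i]]$parent)) {
      rows[[length(rows) + 1]] <- data.frame(
        branch = i, end = "start",
        x = ch$points[1, 1], y = ch$points[1, 2], z = ch$points[1, 3],
        nx = -(ch$points[2, 1] - ch$points[1, 1]),
        ny = -(ch$points[2, 2] - ch$points[1, 2]),
        nz = -(ch$points[2, 3] - ch$points[1, 3]),
        radius = ch$radius[1])
    }
    if (!has_child[i] && !(apex_at_end && identical(apex_host, i))) {
      rows[[length(rows) + 1]] <- data.frame(
        branch = i, end = "end",
        x = ch$points[np, 1], y = ch$points[np, 2], z = ch$points[np, 3],
        nx = ch$points[np, 1] - ch$points[np - 1, 1],
        ny = ch$points[np, 2] - ch$points[np - 1, 2],
        nz = ch$points[np, 3] - ch$points[np - 1, 3],
        radius = ch$radius[np])
    }
  }
  out <- do.call(rbind, rows)
  nn <- rownorms(as.matrix(out[, c("nx", "ny", "nz")]))
  out$nx <- out$nx / nn; out$ny <- out$ny / nn; out$nz <- out$nz / nn
  out
}
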