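#' Per-vessel centerline metrics
#'
#' Length and arc-length-weighted summary statistics (average, minimum,
#' maximum, variance) of radius, curvature and torsion over a branch,
#' optionally restricted to the samples lying within the graph node's
#' segment extent.
#'
#' @param branch a `centerline` with curvature/torsion (see
#'   [frenet_geometry()]).
#' @param node graph node index the branch is assigned to.
#' @param graph optional `vessel_graph`; with `mesh` it masks samples to
#'   the node's segment.
#' @param mesh optional [surface_mesh] for the segment masking.
#' @return A list of class `vessel_metrics`: `node_id`, `level`, `length`,
#'   and `radius`/`curvature`/`torsion` stats (each `avg`, `min`, `max`,
#'   `var`).
#' @export
vessel_metrics <- function(branch, node = NA_integer_, graph = NULL, mesh = NULL) {
  stopifnot(inherits(branch, "centerline"))
  if (nrow(branch$points) < 7) stop("undersampled branch (< 7 points)")
  if (is.null(branch$curvature))
    stop("branch has no curvature; apply frenet_geometry() first")
  n <- nrow(branch$points)
  w <- diff(branch$arclength)
  w <- c(w[1] / 2, (w[-1] + w[-length(w)]) / 2, w[length(w)] / 2)
  keep <- rep(TRUE, n)
  if (!is.null(graph) && !is.null(mesh) && !is.na(node)) {
    vmap <- vertex_segment_map(graph, n_vertices(mesh))
    nnv <- as.vector(RANN::nn2(mesh$vertices, branch$points, k = 1)$nn.idx)
    inseg <- vmap[nnv] == node
    if (sum(inseg, na.rm = TRUE) >= 7) keep <- !is.na(inseg) & inseg
  }
  wstat <- function(x) {
    xk <- x[keep]; wk <- w[keep] / sum(w[keep])
    avg <- sum(wk * xk)
    c(avg = avg, min = min(xk), max = max(xk),
      var = sum(wk * (xk - avg)^2))
  }
  structure(list(
    node_id = if (!is.null(graph) && !is.na(node)) graph$nodes$id[node] else NA_integer_,
    level = if (!is.null(graph) && !is.na(node)) graph$nodes$level[node] else NA_integer_,
    length = branch$arclength[n],
    radius = wstat(branch$radius),
    curvature = wstat(branch$curvature),
    torsion = wstat(branch$torsion)
  ), class = "vessel_metrics")
}

#' Per-level vessel statistics
#'
#' Groups the vessel-like graph nodes by level (up to `max_level`) and
#' reports, per level: the vessel count, the mean vessel length, and
#' pooled radius/curvature/torsion statistics.  Pooling weights each
#' vessel equally: the pooled average is the mean of per-vessel averages,
#' min/max are taken across vessels, and the variance is the
#' between-vessel variance of the per-vessel averages.  Levels with no
#' vessels are omitted.
#'
#' @param graph a level-assigned `vessel_graph`.
#' @param tree a `centerline_tree` with frenet-processed branches and
#'   segment assignment.
#' @param max_level highest level included (default 4).
#' @param mesh optional [surface_mesh] for segment masking of samples.
#' @return data.frame with one row per level.
#' @export
per_level_stats <- function(graph, tree, max_level = 4, mesh = NULL) {
  stopifnot(inherits(graph, "vessel_graph"))
  vl <- which(graph$nodes$class %in% c("VESSEL", "INLET") &
                !is.na(graph$nodes$level) &
                graph$nodes$level <= max_level)
  rows <- list()
  for (lev in sort(unique(graph$nodes$level[vl]))) {
    nodes <- vl[graph$nodes$level[vl] == lev]
    metrics <- list()
    for (nd in nodes) {
      bs <- which(tree$segment_assignment == nd)
      for (b in bs) {
        m <- tryCatch(vessel_metrics(tree$branches[[b]], nd, graph, mesh),
                      error = function(e) NULL)
        if (!is.null(m)) metrics[[length(metrics) + 1]] <- m
      }
    }
    pool <- function(field) {
      if (length(metrics) == 0)
        return(c(avg = NA_real_, min = NA_real_, max = NA_real_, var = NA_real_))
      avgs <- vapply(metrics, function(m) m[[field]][["avg"]], 0)
      c(avg = mean(avgs),
        min = min(vapply(metrics, function(m) m[[field]][["min"]], 0)),
        max = max(vapply(metrics, function(m) m[[field]][["max"]], 0)),
        var = if (length(avgs) > 1) var(avgs) else 0)
    }
    r <- pool("radius"); k <- pool("curvature"); t <- pool("torsion")
    rows[[length(rows) + 1]] <- data.frame(
      level = lev, vessel_count = length(nodes),
      mean_length = if (length(metrics) > 0)
        mean(vapply(metrics, `[[`, 0, "length")) else NA_real_,
      radius_avg = r[["avg"]], radius_min = r[["min"]],
      radius_max = r[["max"]], radius_var = r[["var"]],
      curvature_avg = k[["avg"]], curvature_min = k[["min"]],
      curvature_max = k[["max"]], curvature_var = k[["var"]],
      torsion_avg = t[["avg"]], torsion_min = t[["min"]],
      torsion_max = t[["max"]], torsion_var = t[["var"]])
  }
  do.call(rbind, rows) %||% data.frame()
}

#' Parent-vessel diameter with bifurcation exclusion
#'
#' The aneurysm can widen the parent vessel where it meets the aneurysm
#' bifurcation, so centerline samples lying inside any bifurcation-class
#' segment (in particular the aneurysm bifurcation) are excluded before
#' the diameter is computed as twice the mean (or maximum) inscribed
#' radius.  The start and end of the parent vessel are thereby defined by
#' the bifurcations.  The no-exclusion mode exists as a diagnostic to show
#' the bias the exclusion removes.
#'
#' @param graph a role-refined, level-assigned `vessel_graph`.
#' @param tree a `centerline_tree` with segment assignment.
#' @param mode `"average"` or `"maximum"`.
#' @param exclude_bifurcations mask out samples in bifurcation segments
#'   (default TRUE; FALSE is the diagnostic mode).
#' @param mesh the [surface_mesh] (needed for the masking; defaults to the
#'   tree's field mesh).
#' @return list with `value` (mm; mean over parent vessels) and
#'   `per_vessel` (named numeric, one entry per parent-vessel node).
#' @export
parent_vessel_diameter <- function(graph, tree, mode = c("average", "maximum"),
                                   exclude_bifurcations = TRUE, mesh = NULL) {
  mode <- match.arg(mode)
  mesh <- mesh %||% tree$field$mesh
  pv <- which(graph$nodes$role == "parent_vessel")
  if (length(pv) == 0) stop("no parent_vessel node; refine roles first")
  bif_nodes <- which(graph$nodes$class == "BIFURCATION")
  bif_vertices <- sort(unique(unlist(
    lapply(graph$segments[bif_nodes], `[[`, "vertex_set"))))
  vals <- c()
  for (nd in pv) {
    bs <- which(tree$segment_assignment == nd)
    if (length(bs) == 0) next
    rads <- c()
    for (b in bs) {
      br <- tree$branches[[b]]
      keep <- rep(TRUE, nrow(br$points))
      # near an opening the inscribed sphere is truncated by the cap, not
      # the vessel wall; trim one local radius off each branch end
      L <- br$arclength[length(br$arclength)]
      trim <- min(1.5 * median(br$radius), 0.2 * L)
      keep <- br$arclength > trim & br$arclength < L - trim
      if (exclude_bifurcations && length(bif_vertices) > 0) {
        # a sample lies in the bifurcation section when its own
        # cross-section slab (plane perpendicular to the running tangent)
        # contains bifurcation-class wall vertices
        bv <- mesh$vertices[bif_vertices, , drop = FALSE]
        n <- nrow(br$points)
        tg <- rbind(br$points[2, ] - br$points[1, ],
                    br$points[min(3, n):n, ] - br$points[1:(n - 2), ],
                    br$points[n, ] - br$points[n - 1, ])
        tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
        spacing <- mean(diff(br$arclength))
        slab <- min(max(0.6 * spacing, 0.3), 0.5)
        rmed <- median(br$radius)
        for (i in which(keep)) {
          rel <- sweep(bv, 2, br$points[i, ])
          along <- rel %*% tg[i, ]
          hit <- abs(along) < slab &
            sqrt(rowSums(rel^2)) < 1.45 * rmed + 0.4
          if (any(hit)) keep[i] <- FALSE
        }
      }
      rads <- c(rads, br$radius[keep])
    }
    if (length(rads) == 0) next
    vals[as.character(graph$nodes$id[nd])] <-
      2 * if (mode == "average") mean(rads) else max(rads)
  }
  if (length(vals) == 0)
    stop("all parent-vessel samples were excluded; no diameter measurable")
  list(value = mean(vals), per_vessel = vals, mode = mode,
       excluded_bifurcations = exclude_bifurcations)
}

#' Aneurysm shape indices from the neck curve
#'
#' Computes the classic sac morphometrics: the neck diameter
#' (`2 sqrt(neck planar area / pi)`), the height (maximum signed distance
#' of sac vertices from the neck plane, dome side positive), the width
#' (maximal caliper of the sac vertices in planes parallel to the neck
#' plane), the maximum diameter (largest pairwise sac vertex distance),
#' and the dimensionless rupture-risk ratios: aspect ratio
#' (height / neck diameter), size ratio (height / parent-vessel diameter)
#' and bottleneck factor (width / neck diameter).
#'
#' @param mesh a [surface_mesh].
#' @param neck a `neck_curve` from [extract_neck_curve()].
#' @param parent_diameter parent-vessel diameter in mm (see
#'   [parent_vessel_diameter()]).
#' @param graph a role-refined `vessel_graph` (provides the sac vertices).
#' @return A list of class `aneurysm_shape`.
#' @export
aneurysm_shape <- function(mesh, neck, parent_diameter, graph) {
  stopifnot(inherits(neck, "neck_curve"), inherits(graph, "vessel_graph"))
  an <- which(graph$nodes$role == "aneurysm")
  if (length(an) != 1) stop("graph lacks a single aneurysm node")
  vs <- graph$segments[[an]]$vertex_set
  if (length(vs) < 4) stop("aneurysm segment is empty")
  pts <- mesh$vertices[vs, , drop = FALSE]
  nrm <- neck$normal
  sdist <- as.vector(sweep(pts, 2, neck$center) %*% nrm)
  if (mean(sdist) < 0) { nrm <- -nrm; sdist <- -sdist }  # dome side positive
  height <- max(sdist)
  if (min(sdist) < -0.1 * height)
    warning("aneurysm vertices extend beyond the neck plane on both sides (irregular neck)")
  # width: maximal caliper perpendicular to the height axis
  e1 <- orthogonal_vector(nrm); e2 <- cross3(nrm, e1)
  uv <- cbind(as.vector(sweep(pts, 2, neck$center) %*% e1),
              as.vector(sweep(pts, 2, neck$center) %*% e2))
  hull <- grDevices::chull(uv)
  width <- max(dist(uv[hull, , drop = FALSE]))
  sub <- if (nrow(pts) > 3000) pts[seq(1, nrow(pts), length.out = 3000), ] else pts
  max_diameter <- max(dist(sub))
  neck_diameter <- 2 * neck$equivalent_radius
  structure(list(
    neck_diameter = neck_diameter, height = height, width = width,
    max_diameter = max_diameter,
    parent_vessel_diameter = parent_diameter,
    aspect_ratio = height / neck_diameter,
    size_ratio = height / parent_diameter,
    bottleneck_factor = width / neck_diameter
  ), class = "aneurysm_shape")
}

#' @export
print.aneurysm_shape <- function(x, ...) {
  cat(sprintf(
    paste0("<aneurysm_shape> neck %.2f mm, height %.2f mm, width %.2f mm, ",
           "max diameter %.2f mm\n  aspect ratio %.2f | size ratio %.2f | ",
           "bottleneck factor %.2f\n"),
    x$neck_diameter, x$height, x$width, x$max_diameter,
    x$aspect_ratio, x$size_ratio, x$bottleneck_factor))
  invisible(x)
}
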