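#' Split a labelled mesh into connected same-class segments
#'
#' Connected components of same-class edges (adjacency = shared vertex)
#' become segments.  Each segment gets a numeric id whose hundreds digit
#' encodes the class (1 INLET, 2 ANEURYSM, 3 BIFURCATION, 4 VESSEL) and
#' whose lower digits are a running index assigned in deterministic order:
#' descending edge count, ties broken by the smallest member edge index.
#'
#' @param mesh a [surface_mesh].
#' @param labeling an edge-kind [edge_labeling] (face labelings are
#'   converted first).
#' @return List of `mesh_segment` objects: `numeric_id`, `class`,
#'   `edge_set` (edge indices), `vertex_set`.
#' @export
split_segments <- function(mesh, labeling) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(labeling, "edge_labeling"))
  if (labeling$element_kind == "face") labeling <- convert_labels(mesh, labeling)
  if (length(labeling$labels) != n_edges(mesh))
    stop("label count does not match edge count")
  lab <- as.character(labeling$labels)
  segments <- list()
  for (cls in .seg_classes) {
    eidx <- which(lab == cls)
    if (length(eidx) == 0) next
    # star-link the same-class edges incident to each vertex
    vert <- c(mesh$edges[eidx, 1], mesh$edges[eidx, 2])
    loc <- rep(seq_along(eidx), 2)
    o <- order(vert)
    vv <- vert[o]; ll <- loc[o]
    samev <- which(vv[-1] == vv[-length(vv)])
    g <- igraph::make_empty_graph(n = length(eidx), directed = FALSE)
    if (length(samev) > 0)
      g <- igraph::add_edges(g, rbind(ll[samev], ll[samev + 1]))
    memb <- igraph::components(g)$membership
    comps <- split(eidx, memb)
    sizes <- lengths(comps)
    minidx <- vapply(comps, min, 0L)
    ord <- order(-sizes, minidx)
    if (length(ord) > 99)
      stop("more than 99 ", cls, " segments; numeric-id encoding overflow")
    for (r in seq_along(ord)) {
      es <- comps[[ord[r]]]
      segments[[length(segments) + 1]] <- structure(list(
        numeric_id = 100L * .class_code[[cls]] + r,
        class = cls,
        edge_set = es,
        vertex_set = sort(unique(as.vector(mesh$edges[es, , drop = FALSE])))
      ), class = "mesh_segment")
    }
  }
  segments
}

#' @export
print.mesh_segment <- function(x, ...) {
  cat(sprintf("<mesh_segment %d> %s, %d edges, %d vertices\n",
              x$numeric_id, x$class, length(x$edge_set), length(x$vertex_set)))
  invisible(x)
}

#' Build the part-connection graph of mesh segments
#'
#' Different edge labels meeting at the same vertex indicate a connection
#' between two parts: the graph has one node per segment and an edge
#' between two segments iff at least `min_shared_vertices` vertices carry
#' edges of both.
#'
#' @param mesh a [surface_mesh].
#' @param segments output of [split_segments()].
#' @param min_shared_vertices connection threshold (default 1, the
#'   single-shared-vertex rule; raise to suppress pinch artifacts).
#' @return An object of class `vessel_graph`: `nodes` (data.frame with
#'   `id`, `class`, `role`, `level`), `edges` (data.frame with `from`,
#'   `to`, `shared_vertices`; node indices), and the `segments`.
#' @export
build_part_graph <- function(mesh, segments, min_shared_vertices = 1L) {
  ns <- length(segments)
  covered <- sort(unique(unlist(lapply(segments, `[[`, "edge_set"))))
  if (length(covered) != n_edges(mesh))
    stop("segments do not cover all mesh edges")
  pairs <- do.call(rbind, lapply(seq_len(ns), function(i)
    cbind(segments[[i]]$vertex_set, i)))
  bysv <- split(pairs[, 2], pairs[, 1])
  counts <- new.env(parent = emptyenv())
  for (sv in bysv) {
    if (length(sv) < 2) next
    for (a in seq_len(length(sv) - 1))
      for (b in (a + 1):length(sv)) {
        key <- paste0(sv[a], "_", sv[b])
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
  }
  keys <- ls(counts)
  edges <- if (length(keys) > 0) {
    km <- do.call(rbind, strsplit(keys, "_"))
    data.frame(from = as.integer(km[, 1]), to = as.integer(km[, 2]),
               shared_vertices = vapply(keys, function(k) counts[[k]], 0L),
               row.names = NULL)
  } else data.frame(from = integer(), to = integer(), shared_vertices = integer())
  edges <- edges[edges$shared_vertices >= min_shared_vertices, , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(
    id = vapply(segments, `[[`, 0L, "numeric_id"),
    class = vapply(segments, `[[`, "", "class"),
    role = tolower(vapply(segments, `[[`, "", "class")),
    level = NA_integer_,
    stringsAsFactors = FALSE)
  g <- structure(list(nodes = nodes, edges = edges, segments = segments),
                 class = "vessel_graph")
  if (igraph::components(as_igraph(g))$no > 1)
    warning("part graph is disconnected; the mesh may contain floating components")
  g
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d segments, %d connections\n",
              nrow(x$nodes), nrow(x$edges)))
  info <- sprintf("  %d %s (%s%s)", x$nodes$id, x$nodes$class, x$nodes$role,
                  ifelse(is.na(x$nodes$level), "",
                         paste0(", level ", x$nodes$level)))
  cat(info, sep = "\n")
  invisible(x)
}

#' Convert a vessel graph to igraph
#' @param graph a `vessel_graph`.
#' @return An undirected [igraph::igraph] with node attributes.
#' @export
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$nodes)),
                          numeric_id = graph$nodes$id,
                          class = graph$nodes$class,
                          role = graph$nodes$role,
                          level = ifelse(is.na(graph$nodes$level), -1L,
                                         graph$nodes$level)))
  if (nrow(graph$edges) > 0)
    igraph::E(g)$shared_vertex_count <- graph$edges$shared_vertices
  g
}

graph_neighbors <- function(graph, node) {
  c(graph$edges$to[graph$edges$from == node],
    graph$edges$from[graph$edges$to == node])
}

#' Refine anatomical roles around the aneurysm
#'
#' Bifurcation segments adjacent to the aneurysm become the aneurysm
#' bifurcation (the bifurcation underneath the sac); vessel or inlet
#' segments touching the aneurysm directly become aneurysm vessels; vessel
#' or inlet segments adjacent to the aneurysm bifurcation become parent
#' vessels.  All other class-level roles are preserved.  The operation is
#' idempotent.  With several aneurysm components the largest by edge count
#' is treated as the aneurysm; the others are flagged
#' `aneurysm_secondary`.
#'
#' @param graph a `vessel_graph`.
#' @return The graph with refined `role`s.
#' @export
refine_roles <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  an_all <- which(graph$nodes$class == "ANEURYSM")
  if (length(an_all) == 0)
    stop("no aneurysm segment in the graph; use morphology-only mode (per-level statistics do not require a sac)")
  graph$nodes$role <- tolower(graph$nodes$class)
  if (length(an_all) > 1) {
    sizes <- vapply(graph$segments[an_all], function(s) length(s$edge_set), 0L)
    warning("multiple aneurysm components; the largest is used, ",
            length(an_all) - 1, " flagged as aneurysm_secondary")
    graph$nodes$role[an_all[-which.max(sizes)]] <- "aneurysm_secondary"
    an <- an_all[which.max(sizes)]
  } else an <- an_all
  nb <- graph_neighbors(graph, an)
  bif_nb <- nb[graph$nodes$class[nb] == "BIFURCATION"]
  if (length(bif_nb) > 1) {
    sh <- vapply(bif_nb, function(b) {
      sel <- (graph$edges$from == an & graph$edges$to == b) |
        (graph$edges$to == an & graph$edges$from == b)
      sum(graph$edges$shared_vertices[sel])
    }, 0L)
    warning("several bifurcations touch the aneurysm; the one sharing most vertices is the aneurysm bifurcation")
    bif_nb <- bif_nb[which.max(sh)]
  }
  vessel_nb <- nb[graph$nodes$class[nb] %in% c("VESSEL", "INLET")]
  graph$nodes$role[vessel_nb] <- "aneurysm_vessel"
  if (length(bif_nb) == 1) {
    graph$nodes$role[bif_nb] <- "aneurysm_bifurcation"
    pv <- graph_neighbors(graph, bif_nb)
    pv <- pv[graph$nodes$class[pv] %in% c("VESSEL", "INLET")]
    graph$nodes$role[pv] <- "parent_vessel"
  }
  graph
}

#' Assign vessel levels
#'
#' The level of a vessel-like segment (vessel, inlet, parent vessel,
#' aneurysm vessel) is the number of bifurcation-class segments on the
#' shortest graph path to the aneurysm, floored at 1; the aneurysm itself
#' is level 0.  Unreachable vessels keep an unset level with a warning.
#'
#' @param graph a `vessel_graph` with refined roles.
#' @return The graph with `level`s filled in.
#' @export
assign_levels <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  an <- which(graph$nodes$role == "aneurysm")
  if (length(an) != 1)
    stop("assign_levels needs refined roles with one aneurysm node")
  g <- as_igraph(graph)
  graph$nodes$level <- NA_integer_
  graph$nodes$level[an] <- 0L
  vessel_like <- which(graph$nodes$class %in% c("VESSEL", "INLET"))
  for (v in vessel_like) {
    sp <- suppressWarnings(igraph::shortest_paths(
      g, from = v, to = an, output = "vpath"))$vpath[[1]]
    if (length(sp) == 0) {
      warning("vessel node ", graph$nodes$id[v],
              " unreachable from the aneurysm; level left unset")
      next
    }
    nbif <- sum(graph$nodes$class[as.integer(igraph::as_ids(sp))] == "BIFURCATION")
    graph$nodes$level[v] <- max(1L, nbif)
  }
  graph
}

#' Extract the aneurysm neck curve (ostium)
#'
#' The ostium is the closed curve of vertices shared between the aneurysm
#' segment and its adjacent bifurcation (or, without a collar, vessel)
#' segment, ordered into a cycle along mesh connectivity, with its best-fit
#' plane.
#'
#' @param mesh a [surface_mesh].
#' @param labeling the edge [edge_labeling] (unused directly; retained for
#'   interface symmetry and validation).
#' @param graph a role-refined `vessel_graph`.
#' @return An object of class `neck_curve`: `vertex_cycle`, `points`,
#'   `center`, `normal`, `equivalent_radius`, `planarity`.
#' @export
extract_neck_curve <- function(mesh, labeling, graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (!is.null(labeling) && !any(as.character(labeling$labels) == "ANEURYSM"))
    stop("labeling has no ANEURYSM elements; no neck curve exists")
  an <- which(graph$nodes$role == "aneurysm")
  if (length(an) != 1) stop("graph lacks a single aneurysm node (refine roles first)")
  nb <- which(graph$nodes$role == "aneurysm_bifurcation")
  if (length(nb) == 0) {
    cand <- graph_neighbors(graph, an)
    cand <- cand[graph$nodes$role[cand] == "aneurysm_vessel"]
    if (length(cand) == 0) stop("aneurysm segment has no adjacent bifurcation or vessel")
    sh <- vapply(cand, function(b) {
      sel <- (graph$edges$from == an & graph$edges$to == b) |
        (graph$edges$to == an & graph$edges$from == b)
      sum(graph$edges$shared_vertices[sel])
    }, 0L)
    nb <- cand[which.max(sh)]
  }
  shared <- intersect(graph$segments[[an]]$vertex_set,
                      graph$segments[[nb]]$vertex_set)
  if (length(shared) < 3) stop("fewer than 3 shared neck vertices")
  emask <- mesh$edges[, 1] %in% shared & mesh$edges[, 2] %in% shared
  ep <- mesh$edges[emask, , drop = FALSE]
  le <- matrix(match(ep, shared), ncol = 2)
  cyc <- order_cycle(length(shared), le)
  if (is.null(cyc)) {
    gl <- igraph::graph_from_edgelist(le, directed = FALSE)
    gl <- igraph::add_vertices(gl, max(0L, length(shared) - igraph::vcount(gl)))
    ncomp <- igraph::components(gl)$no
    if (ncomp > 1)
      stop("shared aneurysm/bifurcation vertices do not form a single closed cycle (",
           ncomp, " components)")
    # single ring with chord edges: order the vertices by angle around the
    # best-fit plane instead of walking the (non-simple) connectivity
    pts0 <- mesh$vertices[shared, , drop = FALSE]
    pl <- fit_plane(pts0)
    rel <- sweep(pts0, 2, pl$center)
    e1 <- orthogonal_vector(pl$normal); e2 <- cross3(pl$normal, e1)
    cyc <- order(atan2(rel %*% e2, rel %*% e1))
  }
  vcyc <- shared[cyc]
  pts <- mesh$vertices[vcyc, , drop = FALSE]
  o <- outlet_geometry(pts, kind = "neck")
  structure(list(vertex_cycle = vcyc, points = pts,
                 center = o$center, normal = o$normal,
                 equivalent_radius = o$equivalent_radius,
                 planarity = o$planarity),
            class = "neck_curve")
}

#' @export
print.neck_curve <- function(x, ...) {
  cat(sprintf("<neck_curve> %d vertices, equivalent diameter %.2f mm, planarity %.3f\n",
              length(x$vertex_cycle), 2 * x$equivalent_radius, x$planarity))
  invisible(x)
}

#' Score a predicted segmentation against ground truth
#'
#' @param predicted,truth [edge_labeling]s of the same element kind and
#'   length.
#' @return A list of class `segmentation_score` with `accuracy` (matching
#'   fraction) and `per_class_iou` (intersection over union per class;
#'   `NA` for classes absent from both labelings).
#' @export
segmentation_score <- function(predicted, truth) {
  stopifnot(inherits(predicted, "edge_labeling"), inherits(truth, "edge_labeling"))
  if (predicted$element_kind != truth$element_kind)
    stop("labelings have different element kinds")
  p <- as.character(predicted$labels); t <- as.character(truth$labels)
  if (length(p) != length(t)) stop("labelings have different lengths")
  iou <- vapply(.seg_classes, function(cls) {
    u <- sum(p == cls | t == cls)
    if (u == 0) return(NA_real_)
    sum(p == cls & t == cls) / u
  }, 0)
  structure(list(accuracy = mean(p == t), per_class_iou = iou),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf("<segmentation_score> accuracy %.3f | IoU: %s\n", x$accuracy,
              paste(sprintf("%s %.3f", names(x$per_class_iou), x$per_class_iou),
                    collapse = ", ")))
  invisible(x)
}

#' Geometric four-class labelling from a centerline tree
#'
#' A geometry-driven labelling rule for meshes without an annotated
#' segmentation, so the pipeline runs end-to-end: edges whose midpoint lies
#' farther than `beta` times the local branch radius from every centerline
#' branch are `ANEURYSM` (off-branch surface, i.e. the sac); edges within
#' `alpha` times the radius of at least two branches are `BIFURCATION`;
#' edges nearest the root branch (largest mean radius) are `INLET`; the
#' rest are `VESSEL`.
#'
#' @param mesh a [surface_mesh].
#' @param centerline_tree a `centerline_tree` with radii.
#' @param alpha bifurcation proximity multiplier.
#' @param beta off-branch (aneurysm) distance multiplier.
#' @return An edge-kind [edge_labeling].
#' @export
heuristic_label <- function(mesh, centerline_tree, alpha = 1.5, beta = 1.6) {
  brs <- centerline_tree$branches
  if (length(brs) == 0) stop("empty centerline tree")
  mid <- edge_midpoints(mesh)
  nbranch <- length(brs)
  distm <- matrix(Inf, nrow(mid), nbranch)
  radm <- matrix(1, nrow(mid), nbranch)
  for (b in seq_len(nbranch)) {
    p <- brs[[b]]$points; r <- brs[[b]]$radius
    np <- nrow(p)
    cf <- capsule_field(mid, p[-np, , drop = FALSE], p[-1, , drop = FALSE],
                        rep(0, np - 1), rep(0, np - 1))
    distm[, b] <- cf$distance
    # floor the local radius at the branch median: inscribed spheres are
    # truncated near openings and junctions, which is a property of the
    # caps, not of the vessel calibre
    rloc <- r[cf$segment] + cf$t * (r[pmin(cf$segment + 1L, np)] - r[cf$segment])
    radm[, b] <- pmax(rloc, median(r))
  }
  ratio <- distm / pmax(radm, 1e-9)
  nearest <- max.col(-ratio)
  # the root is the branch seeded at the inlet opening (identified by its
  # enlarged diameter) when known, otherwise the largest-calibre branch
  root <- centerline_tree$root_branch %||%
    which.max(vapply(brs, function(b) mean(b$radius), 0))
  lab <- ifelse(nearest == root, "INLET", "VESSEL")
  near2 <- rowSums(distm <= alpha * radm) >= 2
  lab[near2] <- "BIFURCATION"
  off <- ratio[cbind(seq_len(nrow(mid)), nearest)] > beta
  lab[off] <- "ANEURYSM"
  # collar pass: on-vessel edges hugging the detected sac are the
  # aneurysm bifurcation (crossover section between vessel and sac)
  if (any(off) && !all(off)) {
    dsac <- RANN::nn2(mid[off, , drop = FALSE], mid, k = 1)$nn.dists[, 1]
    mel <- mean(rownorms(mesh$vertices[mesh$edges[, 1], , drop = FALSE] -
                           mesh$vertices[mesh$edges[, 2], , drop = FALSE]))
    lab[!off & lab != "BIFURCATION" & dsac < 3 * mel] <- "BIFURCATION"
  }
  edge_labeling(lab, "edge", mesh = mesh)
}

#' Write a vessel graph to GraphML (and an optional JSON mirror)
#'
#' @param graph a `vessel_graph`.
#' @param path output `.graphml` path.
#' @param json_path optional JSON mirror path.
#' @return `path`, invisibly.
#' @export
write_vessel_graph <- function(graph, path, json_path = NULL) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  if (!is.null(json_path)) {
    jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges),
                         json_path, dataframe = "rows", na = "null")
  }
  invisible(path)
}

# vertex index -> graph node index map (majority of incident segment edges)
vertex_segment_map <- function(graph, n_vertices) {
  vmap <- rep(NA_integer_, n_vertices)
  # larger segments win contested boundary vertices
  ord <- order(-vapply(graph$segments, function(s) length(s$edge_set), 0L))
  for (i in rev(ord)) vmap[graph$segments[[i]]$vertex_set] <- i
  vmap
}
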