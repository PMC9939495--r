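#' Pipeline configuration
#'
#' Validates and completes the configuration for [run_pipeline()].
#' Unknown keys are rejected; every parameter is bounds-checked before any
#' stage runs.
#'
#' @param mesh path to the input surface mesh.
#' @param labels optional path to a label sidecar (CSV/JSON); without it
#'   the geometric [heuristic_label()] stand-in is used.
#' @param output_dir directory for pipeline artifacts.
#' @param seed RNG seed used by every stochastic step.
#' @param neighborhood_radius local PCA neighbourhood (mm) for cutting.
#' @param extrusion_factor flow-extension length in local diameters.
#' @param angle_tolerance closed-outlet dihedral tolerance (degrees).
#' @param resample_step centerline resampling step (mm; `NULL` = auto).
#' @param alpha,beta [heuristic_label()] multipliers.
#' @param max_level highest vessel level reported.
#' @param min_shared_vertices part-graph connection threshold.
#' @param pitch inscribed-sphere lattice pitch (mm; `NULL` = auto).
#' @param cut_seeds optional integer vector of seed vertices to cut+extrude
#'   before analysis.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mesh, labels = NULL, output_dir = tempfile("aneugraph_"),
                            seed = 1L, neighborhood_radius = 3,
                            extrusion_factor = 5, angle_tolerance = 20,
                            resample_step = NULL, alpha = 1.5, beta = 1.6,
                            max_level = 4, min_shared_vertices = 1L,
                            pitch = NULL, cut_seeds = NULL,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(is.character(mesh), length(mesh) == 1)
  if (neighborhood_radius <= 0) stop("neighborhood_radius must be > 0")
  if (extrusion_factor < 0) stop("extrusion_factor must be >= 0")
  if (angle_tolerance <= 0 || angle_tolerance >= 90)
    stop("angle_tolerance must lie in (0, 90) degrees")
  if (!is.null(resample_step) && resample_step <= 0) stop("resample_step must be > 0")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  if (max_level < 1) stop("max_level must be >= 1")
  if (min_shared_vertices < 1) stop("min_shared_vertices must be >= 1")
  if (!is.null(pitch) && pitch <= 0) stop("pitch must be > 0")
  structure(list(mesh = mesh, labels = labels, output_dir = output_dir,
                 seed = as.integer(seed),
                 neighborhood_radius = neighborhood_radius,
                 extrusion_factor = extrusion_factor,
                 angle_tolerance = angle_tolerance,
                 resample_step = resample_step, alpha = alpha, beta = beta,
                 max_level = max_level,
                 min_shared_vertices = as.integer(min_shared_vertices),
                 pitch = pitch, cut_seeds = cut_seeds,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with `pipeline_config()` keys.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, cfg)
}

#' Run the full vessel analysis pipeline
#'
#' Chains every stage: mesh validation, optional cutting with flow
#' extension, labelling (sidecar or geometric stand-in), segment split and
#' semantic graph with refined roles and levels, outlet detection (open
#' boundary loops, falling back to dihedral-angle detection on watertight
#' meshes), per-segment centerlines with curvature/torsion, and the
#' morphology report.  Every artifact is written to the output directory
#' and listed in a manifest with md5 checksums; the same config and seed
#' reproduce identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return The manifest: list with `artifacts` (data.frame of path, md5),
#'   `config`, and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  logi <- function(stage, ...) {
    if (config$log_level == "info")
      message(sprintf("[aneugraph %s] %s", stage, sprintf(...)))
  }
  set.seed(config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  mesh <- stage("read", read_mesh(config$mesh))
  report <- validate_mesh(mesh)
  logi("validate", "%d vertices, watertight: %s, boundary edges: %d",
       n_vertices(mesh), report$is_watertight, report$boundary_edge_count)
  if (!report$is_edge_manifold)
    stop("pipeline stage 'validate' failed: mesh is not edge-manifold; repair the segmentation output")

  if (!is.null(config$cut_seeds)) {
    for (sv in config$cut_seeds) {
      fr <- stage("cut", local_frame(mesh, sv, config$neighborhood_radius))
      mesh <- stage("cut", cut_and_extrude(mesh, fr, config$extrusion_factor))
      logi("cut", "seed %d: local diameter %.2f mm, extruded %.1f mm",
           sv, fr$local_diameter, config$extrusion_factor * fr$local_diameter)
    }
  }

  outlets <- stage("outlets", {
    loops <- find_boundary_loops(mesh)
    if (length(loops) > 0) {
      ol <- lapply(loops, outlet_geometry, mesh = mesh)
      radii <- vapply(ol, `[[`, 0, "equivalent_radius")
      for (i in seq_along(ol)) ol[[i]]$candidate_inlet <- i == which.max(radii)
      ol
    } else {
      detect_closed_outlets(mesh, config$angle_tolerance)
    }
  })
  logi("outlets", "%d openings detected", length(outlets))
  if (length(outlets) < 2)
    stop("pipeline stage 'outlets' failed: fewer than 2 openings; open or cap the vessel ends")

  field <- stage("centerline", medial_field(mesh, pitch = config$pitch))
  tree <- stage("centerline",
                compute_centerline_tree(mesh, outlets, field = field))
  logi("centerline", "%d branches over %d interior sites",
       length(tree$branches), nrow(field$sites))

  labeling <- stage("label", {
    if (!is.null(config$labels)) {
      lb <- read_labels(config$labels, mesh = mesh)
      if (lb$element_kind == "face") lb <- convert_labels(mesh, lb) else lb
    } else {
      logi("label", "no sidecar given; geometric stand-in labelling (alpha=%.2f, beta=%.2f)",
           config$alpha, config$beta)
      heuristic_label(mesh, tree, alpha = config$alpha, beta = config$beta)
    }
  })

  segments <- stage("graph", split_segments(mesh, labeling))
  graph <- stage("graph", build_part_graph(mesh, segments,
                                           config$min_shared_vertices))
  has_aneurysm <- any(graph$nodes$class == "ANEURYSM")
  if (has_aneurysm) {
    graph <- stage("graph", refine_roles(graph))
    graph <- stage("graph", assign_levels(graph))
  } else logi("graph", "no aneurysm segment; morphology-only mode (no roles/levels)")
  logi("graph", "%d segments, %d connections", nrow(graph$nodes), nrow(graph$edges))

  tree <- assign_tree_segments(tree, graph)
  tree_raw <- tree  # dense lattice-resolution branches for diameter work
  tree <- stage("frenet", tree_frenet(tree, resample_step = config$resample_step))

  morpho <- list()
  if (has_aneurysm) {
    morpho$per_level <- stage("morphology",
                              per_level_stats(graph, tree, config$max_level, mesh = mesh))
    morpho$neck <- tryCatch(extract_neck_curve(mesh, labeling, graph),
                            error = function(e) { logi("morphology", "neck: %s",
                                                       conditionMessage(e)); NULL })
    morpho$parent_diameter <- tryCatch(parent_vessel_diameter(graph, tree_raw, mesh = mesh),
                                       error = function(e) NULL)
    if (!is.null(morpho$neck) && !is.null(morpho$parent_diameter))
      morpho$shape <- stage("morphology",
                            aneurysm_shape(mesh, morpho$neck,
                                           morpho$parent_diameter$value, graph))
  }

  # exports
  paths <- c(graph = file.path(config$output_dir, "graph.graphml"),
             graph_json = file.path(config$output_dir, "graph.json"),
             outlets = file.path(config$output_dir, "outlets.json"),
             centerlines = file.path(config$output_dir, "centerlines.csv"),
             labels = file.path(config$output_dir, "labels.csv"),
             report = file.path(config$output_dir, "report.json"))
  stage("export", {
    write_vessel_graph(graph, paths[["graph"]], paths[["graph_json"]])
    jsonlite::write_json(outlets_table(outlets), paths[["outlets"]],
                         dataframe = "rows", digits = NA)
    write.csv(centerlines_table(tree), paths[["centerlines"]], row.names = FALSE)
    write_labels(labeling, paths[["labels"]])
    rep <- list(
      validation = unclass(report),
      n_outlets = length(outlets),
      levels = if (!is.null(morpho$per_level)) morpho$per_level else NULL,
      parent_vessel_diameter = if (!is.null(morpho$parent_diameter))
        morpho$parent_diameter$value else NULL,
      shape = if (!is.null(morpho$shape)) unclass(morpho$shape) else NULL)
    jsonlite::write_json(rep, paths[["report"]], dataframe = "rows",
                         auto_unbox = TRUE, digits = 10, na = "null")
  })
  manifest <- data.frame(artifact = names(paths), path = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))),
                         row.names = NULL)
  logi("done", "%d artifacts in %s (%.1f s)", nrow(manifest), config$output_dir,
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(artifacts = manifest, config = config, mesh = mesh,
                 validation = report, outlets = outlets, labeling = labeling,
                 graph = graph, tree = tree, morphology = morpho))
}

#' Centerline tree as a flat table
#'
#' @param tree a `centerline_tree`.
#' @return data.frame `branch_id,s,x,y,z,radius,curvature,torsion`.
#' @export
centerlines_table <- function(tree) {
  do.call(rbind, lapply(seq_along(tree$branches), function(b) {
    br <- tree$branches[[b]]
    data.frame(branch_id = b, s = round(br$arclength, 9),
               x = round(br$points[, 1], 9), y = round(br$points[, 2], 9),
               z = round(br$points[, 3], 9), radius = round(br$radius, 9),
               curvature = if (is.null(br$curvature)) NA else round(br$curvature, 9),
               torsion = if (is.null(br$torsion)) NA else round(br$torsion, 9))
  }))
}
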