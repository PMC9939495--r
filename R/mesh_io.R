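#' Read a vascular surface mesh
#'
#' Reads OBJ, OFF, PLY (ascii and binary little-endian) and STL (ascii and
#' binary) triangle meshes.  Units are taken to be millimetres; no unit
#' metadata is read.  OBJ/OFF/PLY 0/1-based index conventions are converted
#' to R's 1-based indexing.  Duplicate vertices are merged at a tolerance of
#' `1e-6` mm (STL dialects duplicate vertices per facet).
#'
#' @param path path to the mesh file.
#' @param format optional format tag (`"obj"`, `"off"`, `"ply"`, `"stl"`);
#'   inferred from the file extension when missing.
#' @return A [surface_mesh].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  raw <- switch(format,
    obj = read_obj(path),
    off = read_off(path),
    ply = read_ply(path),
    stl = read_stl(path),
    stop("unsupported mesh format: '", format, "' (expected obj/off/ply/stl)"))
  if (nrow(raw$vertices) == 0 || nrow(raw$triangles) == 0)
    stop("empty mesh in ", path)
  surface_mesh(raw$vertices, raw$triangles)
}

#' Write a surface mesh
#'
#' @param mesh a [surface_mesh].
#' @param path output path; extension selects the format unless `format` is
#'   given.
#' @param format one of `"obj"`, `"off"`, `"ply"`, `"stl"`.
#' @param binary write binary PLY (little-endian) / binary STL instead of
#'   ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    obj = write_obj(mesh, path),
    off = write_off(mesh, path),
    ply = write_ply(mesh, path, binary = binary),
    stl = write_stl(mesh, path, binary = binary),
    stop("unsupported mesh format: '", format, "'"))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  tris <- lapply(seq_along(flines), function(i) {
    toks <- strsplit(trimws(sub("^f", "", flines[i])), "\\s+")[[1]]
    idx <- suppressWarnings(as.integer(sub("/.*", "", toks)))
    if (anyNA(idx)) stop("unparseable OBJ face line: '", flines[i], "'")
    if (length(idx) < 3) stop("OBJ face with <3 vertices: '", flines[i], "'")
    cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])  # fan
  })
  list(vertices = verts, triangles = do.call(rbind, tris))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
}

read_off <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toupper(toks[1]) != "OFF") stop("not an OFF file (missing OFF header): ", path)
  nv <- as.integer(toks[2]); nf <- as.integer(toks[3])
  ptr <- 5L
  verts <- matrix(as.numeric(toks[ptr:(ptr + 3 * nv - 1)]), nv, 3, byrow = TRUE)
  ptr <- ptr + 3L * nv
  tris <- vector("list", nf)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[ptr])
    idx <- as.integer(toks[(ptr + 1):(ptr + k)]) + 1L
    if (k < 3) stop("OFF face with <3 vertices at face ", i)
    tris[[i]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
    ptr <- ptr + k + 1L
  }
  list(vertices = verts, triangles = do.call(rbind, tris))
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("PLY header not terminated in ", path)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]

  # parse element/property declarations
  elems <- list(); cur <- NULL
  for (ln in header) {
    t <- strsplit(trimws(ln), "\\s+")[[1]]
    if (t[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = t[2], count = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1L]] <-
        if (t[2] == "list") list(list = TRUE, count_type = t[3], type = t[4], name = t[5])
        else list(list = FALSE, type = t[2], name = t[3])
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY file lacks vertex/face elements: ", path)

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
                 int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(type, n = 1) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n = n, size = sz, endian = "little")
    else
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(sz < 4 && grepl("^u", type)))
  }

  if (fmt == "ascii") {
    toks <- scan(con, what = character(), quiet = TRUE)
    ptr <- 1L
    nv <- elems$vertex$count
    np <- length(elems$vertex$props)
    vprop_names <- vapply(elems$vertex$props, `[[`, "", "name")
    vdat <- matrix(as.numeric(toks[ptr:(ptr + nv * np - 1)]), nv, np, byrow = TRUE)
    ptr <- ptr + nv * np
    verts <- vdat[, match(c("x", "y", "z"), vprop_names), drop = FALSE]
    nf <- elems$face$count
    tris <- vector("list", nf)
    for (i in seq_len(nf)) {
      k <- as.integer(toks[ptr])
      idx <- as.integer(toks[(ptr + 1):(ptr + k)]) + 1L
      tris[[i]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
      ptr <- ptr + k + 1L
    }
    return(list(vertices = verts, triangles = do.call(rbind, tris)))
  }
  if (fmt != "binary_little_endian")
    stop("unsupported PLY format '", fmt, "' in ", path)

  nv <- elems$vertex$count
  vprops <- elems$vertex$props
  vprop_names <- vapply(vprops, `[[`, "", "name")
  vdat <- matrix(NA_real_, nv, length(vprops))
  # vertices: read row-wise to honour arbitrary property layouts
  for (i in seq_len(nv))
    for (p in seq_along(vprops))
      vdat[i, p] <- read_scalar(vprops[[p]]$type)
  verts <- vdat[, match(c("x", "y", "z"), vprop_names), drop = FALSE]
  nf <- elems$face$count
  fprops <- elems$face$props
  tris <- vector("list", nf)
  for (i in seq_len(nf)) {
    for (p in seq_along(fprops)) {
      pr <- fprops[[p]]
      if (pr$list) {
        k <- read_scalar(pr$count_type)
        idx <- read_scalar(pr$type, n = k)
        if (pr$name %in% c("vertex_indices", "vertex_index")) {
          idx <- as.integer(idx) + 1L
          tris[[i]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
        }
      } else read_scalar(pr$type)
    }
  }
  list(vertices = verts, triangles = do.call(rbind, tris))
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(mesh$triangles[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                       mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  }
}

read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 512)
  txt <- rawToChar(hdr[hdr != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) %% 3 != 0)
      stop("ascii STL vertex count not a multiple of 3 in ", path)
    coords <- do.call(rbind, lapply(
      strsplit(trimws(sub("vertex", "", vlines)), "\\s+"),
      function(x) as.numeric(x[1:3])))
    nf <- nrow(coords) / 3
    tris <- matrix(seq_len(3 * nf), nf, 3, byrow = TRUE)
    return(list(vertices = coords, triangles = tris))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", size = 4, endian = "little")
  if (is.na(nf) || nf <= 0) stop("binary STL with invalid facet count: ", path)
  body <- readBin(con, "raw", n = nf * 50)
  if (length(body) < nf * 50) stop("binary STL truncated: ", path)
  idx <- rep(seq(0, by = 50, length.out = nf), each = 48) +
    rep(1:48, times = nf)
  fl <- readBin(body[idx], "double", size = 4, n = nf * 12, endian = "little")
  fl <- matrix(fl, nf, 12, byrow = TRUE)
  coords <- rbind(fl[, 4:6], fl[, 7:9], fl[, 10:12])
  # interleave the three per-face vertex blocks into v1,v2,v3 face order
  ord <- as.vector(t(matrix(seq_len(3 * nf), nf, 3)))
  coords <- coords[ord, , drop = FALSE]
  tris <- matrix(seq_len(3 * nf), nf, 3, byrow = TRUE)
  list(vertices = coords, triangles = tris)
}

write_stl <- function(mesh, path, binary = FALSE) {
  nrm <- face_normals(mesh)
  v <- mesh$vertices; tr <- mesh$triangles
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(tr))) {
      writeBin(c(nrm[i, ], v[tr[i, 1], ], v[tr[i, 2], ], v[tr[i, 3], ]),
               con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(tr))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[tr[i, ], 1], v[tr[i, ], 2], v[tr[i, ], 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
}

#' Per-element class labels over the four-part segmentation scheme
#'
#' The four classes are `INLET` (inlet vessel, enlarged diameter),
#' `ANEURYSM` (the sac), `BIFURCATION` (crossover sections between vessels
#' or between vessel and aneurysm) and `VESSEL` (all remaining vessels).
#' Labels attach either to mesh edges (the native scheme downstream) or to
#' faces (the common output of face-based tools; convert with
#' [convert_labels()]).
#'
#' @param labels character vector of class names, one per edge or face.
#' @param element_kind `"edge"` or `"face"`.
#' @param mesh optional [surface_mesh] used to validate the label count.
#' @return An object of class `edge_labeling`.
#' @export
edge_labeling <- function(labels, element_kind = c("edge", "face"), mesh = NULL) {
  element_kind <- match.arg(element_kind)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .seg_classes)
  if (length(bad) > 0 || anyNA(labels))
    stop("labels outside the class set {", paste(.seg_classes, collapse = ", "),
         "}: ", paste(bad, collapse = ", "))
  if (!is.null(mesh)) {
    expected <- if (element_kind == "edge") n_edges(mesh) else n_faces(mesh)
    if (length(labels) != expected)
      stop("label count (", length(labels), ") does not match ",
           element_kind, " count (", expected, ")")
  }
  structure(list(labels = factor(labels, levels = .seg_classes),
                 element_kind = element_kind),
            class = "edge_labeling")
}

#' @export
print.edge_labeling <- function(x, ...) {
  cat(sprintf("<edge_labeling> %d %s labels: %s\n", length(x$labels),
              x$element_kind,
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Convert face labels to edge labels
#'
#' Each edge takes the label of its incident faces.  Where the two incident
#' faces disagree the transition class wins, in priority order
#' `BIFURCATION` > `ANEURYSM` > `INLET` > `VESSEL`: disagreement zones
#' between parts are exactly what the bifurcation class models.
#'
#' @param mesh a [surface_mesh].
#' @param labeling a face [edge_labeling].
#' @return An edge-kind [edge_labeling].
#' @export
convert_labels <- function(mesh, labeling) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(labeling, "edge_labeling"))
  if (labeling$element_kind != "face")
    stop("convert_labels expects a face labeling")
  if (length(labeling$labels) != n_faces(mesh))
    stop("label count (", length(labeling$labels),
         ") does not match face count (", n_faces(mesh), ")")
  priority <- c(BIFURCATION = 1L, ANEURYSM = 2L, INLET = 3L, VESSEL = 4L)
  fl <- as.character(labeling$labels)
  l1 <- fl[mesh$edge_faces[, 1]]
  l2 <- ifelse(is.na(mesh$edge_faces[, 2]), l1, fl[mesh$edge_faces[, 2]])
  out <- ifelse(priority[l1] <= priority[l2], l1, l2)
  edge_labeling(out, "edge", mesh = mesh)
}

#' Read / write label sidecar files
#'
#' CSV sidecars have the header `element_kind,index,class` with 0-based
#' `index` into the face list or into the lexicographically sorted unordered
#' edge list (that ordering is part of the file contract).  JSON sidecars
#' are `{"element_kind": "...", "labels": [...]}` with labels in element
#' order.
#'
#' @param path file path (`.csv` or `.json`).
#' @param mesh optional [surface_mesh] for count validation.
#' @return An [edge_labeling].
#' @export
read_labels <- function(path, mesh = NULL) {
  if (!file.exists(path)) stop("label file does not exist: ", path)
  if (tolower(tools::file_ext(path)) == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(edge_labeling(j$labels, j$element_kind, mesh = mesh))
  }
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("element_kind", "index", "class")
  if (!all(need %in% names(d)))
    stop("label CSV must have header element_kind,index,class: ", path)
  kind <- unique(d$element_kind)
  if (length(kind) != 1) stop("mixed element kinds in ", path)
  labels <- character(nrow(d))
  labels[d$index + 1L] <- d$class
  if (any(labels == "")) stop("label CSV has gaps in its index column: ", path)
  edge_labeling(labels, kind, mesh = mesh)
}

#' @param labeling an [edge_labeling] to write.
#' @rdname read_labels
#' @export
write_labels <- function(labeling, path) {
  stopifnot(inherits(labeling, "edge_labeling"))
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(
      list(element_kind = labeling$element_kind,
           labels = as.character(labeling$labels)),
      path, auto_unbox = TRUE)
  } else {
    d <- data.frame(element_kind = labeling$element_kind,
                    index = seq_along(labeling$labels) - 1L,
                    class = as.character(labeling$labels))
    write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
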