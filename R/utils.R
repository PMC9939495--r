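# Small vector-geometry helpers shared across modules.

vnorm <- function(x) sqrt(sum(x^2))

unitize <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  x / n
}

rownorms <- function(m) sqrt(rowSums(m^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product of two n x 3 matrices
cross3m <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# any unit vector orthogonal to v
orthogonal_vector <- function(v) {
  v <- unitize(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitize(cross3(v, ref))
}

# Best-fit plane through points (n x 3): centroid + unit normal
# (smallest-variance principal axis).
fit_plane <- function(pts) {
  stopifnot(nrow(pts) >= 3)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0)
  list(center = ctr, normal = sv$v[, 3])
}

# Area of a closed 3D polygon (vertices in order) via the vector area.
polygon_area3 <- function(pts) {
  n <- nrow(pts)
  nxt <- c(2:n, 1)
  s <- colSums(cross3m(pts, pts[nxt, , drop = FALSE]))
  vnorm(s) / 2
}

# Order an n x 3 point loop given an adjacency edge list (rows of vertex
# index pairs into 1..n); returns the ordered index cycle or NULL if the
# edges do not form a single simple cycle.
order_cycle <- function(n, edge_pairs) {
  if (nrow(edge_pairs) != n) return(NULL)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edge_pairs))) {
    a <- edge_pairs[r, 1]; b <- edge_pairs[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  if (any(lengths(adj) != 2)) return(NULL)
  cyc <- integer(n)
  cyc[1] <- 1L
  cyc[2] <- adj[[1]][1]
  for (i in 3:n) {
    nbrs <- adj[[cyc[i - 1]]]
    nxt <- nbrs[nbrs != cyc[i - 2]][1]
    if (is.na(nxt)) return(NULL)
    cyc[i] <- nxt
  }
  if (!(cyc[1] %in% adj[[cyc[n]]]) || anyDuplicated(cyc)) return(NULL)
  cyc
}

# cumulative arc length of an ordered polyline (n x 3)
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(rownorms(diff(pts))))
}

# resample an open polyline to points spaced ~step along arc length
resample_polyline <- function(pts, step = NULL, n_out = NULL) {
  s <- polyline_arclength(pts)
  L <- s[length(s)]
  if (is.null(n_out)) n_out <- max(2L, as.integer(round(L / step)) + 1L)
  si <- seq(0, L, length.out = n_out)
  out <- matrix(0, n_out, 3)
  for (d in 1:3) out[, d] <- approx(s, pts[, d], xout = si, ties = "ordered")$y
  list(points = out, arclength = si)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
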