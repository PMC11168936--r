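#' Construct a surface mesh
#'
#' Triangular surface mesh of a segmented organ: vertex coordinates in
#' micrometres and faces as 1-based vertex index triples. Degenerate
#' (zero-area) faces are dropped on construction with a warning.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of vertex indices.
#' @param organ_name,specimen_id metadata strings.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, organ_name = "organ",
                         specimen_id = "specimen") {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must have 3 columns")
  if (nrow(vertices) < 4L) stopf("a mesh needs at least 4 vertices")
  if (ncol(faces) != 3L) stopf("faces must be triangles (3 columns)")
  if (nrow(faces) < 1L) stopf("mesh has no faces")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stopf("face indices out of range [1, %d]", nrow(vertices))
  }
  area2 <- face_areas2(vertices, faces)
  if (any(area2 <= 0)) {
    warnf("dropping %d degenerate (zero-area) face(s)", sum(area2 <= 0))
    faces <- faces[area2 > 0, , drop = FALSE]
    if (nrow(faces) < 1L) stopf("all faces degenerate")
  }
  structure(list(vertices = vertices, faces = faces,
                 organ_name = organ_name, specimen_id = specimen_id),
            class = "surface_mesh")
}

face_areas2 <- function(v, f) {
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh '%s' (%s): %d vertices, %d faces\n",
              x$organ_name, x$specimen_id, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a Wavefront OBJ mesh
#'
#' Parses `v` and `f` records (texture/normal indices after `/` are
#' ignored); all other records are skipped. Faces must be triangles.
#'
#' @param path path to the OBJ file.
#' @param ... metadata passed to [surface_mesh()].
#' @return a [surface_mesh()].
#' @export
read_obj <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  tok <- strsplit(trimws(lines), "\\s+")
  kind <- vapply(tok, function(t) if (length(t)) t[[1L]] else "", character(1L))
  vi <- which(kind == "v"); fi <- which(kind == "f")
  if (!length(vi)) stopf("no vertices in %s", path)
  if (!length(fi)) stopf("no faces in %s", path)
  verts <- matrix(NA_real_, length(vi), 3L)
  for (r in seq_along(vi)) {
    t <- tok[[vi[r]]]
    if (length(t) < 4L) stopf("malformed vertex at line %d of %s", vi[r], path)
    v <- suppressWarnings(as.numeric(t[2:4]))
    if (any(is.na(v))) stopf("non-numeric vertex at line %d of %s", vi[r], path)
    verts[r, ] <- v
  }
  faces <- matrix(NA_integer_, length(fi), 3L)
  for (r in seq_along(fi)) {
    t <- tok[[fi[r]]]
    if (length(t) != 4L) stopf("face at line %d of %s is not a triangle", fi[r], path)
    idx <- suppressWarnings(as.integer(sub("/.*", "", t[2:4])))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > nrow(verts))) {
      stopf("malformed face indices at line %d of %s", fi[r], path)
    }
    faces[r, ] <- idx
  }
  surface_mesh(verts, faces, ...)
}

#' Write a Wavefront OBJ mesh
#'
#' Emits plain `v`/`f` records.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c(sprintf("# OBJ mesh %s (%s), units um", mesh$organ_name, mesh$specimen_id),
               sprintf("v %.10g %.10g %.10g", v[, 1L], v[, 2L], v[, 3L]),
               sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L])),
             path)
  invisible(path)
}

# Exact nearest-neighbour distances from each row of `from` to the rows of
# `to`, computed blockwise so large vertex sets stay within memory. Returns
# distances with the matched indices in attribute "index".
nearest_distance <- function(from, to, block = 2048L) {
  from <- as.matrix(from); to <- as.matrix(to)
  n <- nrow(from)
  to_sq <- rowSums(to * to)
  d2 <- numeric(n); idx <- integer(n)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    Fb <- from[rows, , drop = FALSE]
    # squared cross distances via the expansion |f - t|^2 = |f|^2 - 2 f.t + |t|^2
    G <- -2 * Fb %*% t(to)
    G <- sweep(G, 2L, to_sq, `+`)
    G <- G + rowSums(Fb * Fb)
    wi <- max.col(-G, ties.method = "first")
    idx[rows] <- wi
    d2[rows] <- G[cbind(seq_along(rows), wi)]
  }
  structure(sqrt(pmax(d2, 0)), index = idx)
}

#' Minimal vertex-to-vertex distances between two organ meshes
#'
#' For each vertex of `organ_x`, the Euclidean distance to its nearest
#' vertex on `organ_y` (exact nearest neighbours, identical to brute-force
#' all-pairs). The result doubles as a per-vertex proximity heatmap.
#'
#' @param organ_x,organ_y [surface_mesh()]es.
#' @param warn_vertices emit a warning above this vertex count (undecimated
#'   meshes are usually the caller's mistake).
#' @return numeric vector of length `nrow(organ_x$vertices)`; the matched
#'   vertex indices on `organ_y` are in attribute `"index"`.
#' @export
min_vertex_distances <- function(organ_x, organ_y, warn_vertices = 1e5) {
  stopifnot(inherits(organ_x, "surface_mesh"), inherits(organ_y, "surface_mesh"))
  nx <- nrow(organ_x$vertices); ny <- nrow(organ_y$vertices)
  if (nx > warn_vertices || ny > warn_vertices) {
    warnf("mesh has over %g vertices; consider decimating before proximity analysis", warn_vertices)
  }
  nearest_distance(organ_x$vertices, organ_y$vertices)
}

#' Per-vertex proximity heatmap table
#'
#' @param organ_x,organ_y [surface_mesh()]es.
#' @return data frame (vertex_id, distance) for export alongside the mesh.
#' @export
proximity_heatmap <- function(organ_x, organ_y) {
  d <- min_vertex_distances(organ_x, organ_y)
  data.frame(vertex_id = seq_along(d), distance = as.numeric(d))
}

#' Centreline-referenced proximity profile
#'
#' Resamples the gut centreline to `n_points` equally spaced points, links
#' each point to its `k_nearest` gut-mesh vertices, and assigns the point
#' the minimum over those vertices of their nearest distance to the target
#' organ. This plots interorgan proximity as a function of position along
#' the gut; restrict to the loop region by subsetting the curve with
#' [subset_by_landmarks()] first.
#'
#' @param gut_curve `param_curve` of the gut.
#' @param gut_mesh [surface_mesh()] of the gut (matching the curve).
#' @param organ [surface_mesh()] of the target organ.
#' @param n_points number of profile points (default 100).
#' @param k_nearest gut vertices linked per centreline point (default 20,
#'   clipped to the vertex count with a warning).
#' @return an object of class `proximity_profile`: data frame with columns
#'   `point` (1..n_points), `position` (fraction of length), `distance`
#'   (micrometres), plus organ names in attributes.
#' @export
centreline_proximity <- function(gut_curve, gut_mesh, organ,
                                 n_points = 100L, k_nearest = 20L) {
  gut_curve <- parameterize(gut_curve)
  stopifnot(inherits(gut_mesh, "surface_mesh"), inherits(organ, "surface_mesh"))
  nv <- nrow(gut_mesh$vertices)
  if (k_nearest > nv) {
    warnf("k_nearest = %d exceeds the gut mesh vertex count %d; clipped", k_nearest, nv)
    k_nearest <- nv
  }
  pts <- unclass(resample_equal(gut_curve, n_points))
  vdist <- min_vertex_distances(gut_mesh, organ)
  prof <- numeric(n_points)
  to <- gut_mesh$vertices
  to_sq <- rowSums(to * to)
  for (i in seq_len(n_points)) {
    d2 <- to_sq - 2 * drop(to %*% pts[i, ]) + sum(pts[i, ]^2)
    near <- order(d2)[seq_len(k_nearest)]
    prof[i] <- min(vdist[near])
  }
  structure(data.frame(point = seq_len(n_points),
                       position = seq(0, 1, length.out = n_points),
                       distance = prof),
            gut = gut_mesh$organ_name, organ = organ$organ_name,
            specimen_id = gut_curve$specimen_id,
            class = c("proximity_profile", "data.frame"))
}

#' Contact calling across a cohort
#'
#' A specimen is scored as a contact if the minimum of its proximity profile
#' falls below `threshold`; the cohort contact frequency is the fraction of
#' contacts. The threshold is a reporting choice (default 5 um) and is
#' echoed in the output.
#'
#' @param profiles list of [centreline_proximity()] profiles (or numeric
#'   vectors of distances).
#' @param threshold contact distance threshold in micrometres (> 0).
#' @return list with `contact` (logical per specimen), `frequency`,
#'   `n_contact`, `n_total` and `threshold`.
#' @export
contact_call <- function(profiles, threshold = 5) {
  if (!length(profiles)) stopf("empty cohort")
  if (!is.numeric(threshold) || threshold <= 0) stopf("threshold must be positive")
  mins <- vapply(profiles, function(p) {
    if (is.data.frame(p)) min(p$distance) else min(as.numeric(p))
  }, 1)
  contact <- mins < threshold
  list(contact = contact, frequency = mean(contact),
       n_contact = sum(contact), n_total = length(contact),
       threshold = threshold)
}
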