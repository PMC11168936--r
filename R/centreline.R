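#' Construct a centreline
#'
#' A centreline is an ordered, unbranched 3D polyline traced through the
#' middle of a tubular organ, with coordinates in micrometres and optional
#' named anatomical landmarks (conventionally `loop_start`, `loop_end` and
#' `R3`) that delimit gut regions. The first point is the anterior end.
#'
#' @param points numeric matrix with one row per point and columns x, y, z
#'   (micrometres), ordered anterior to posterior.
#' @param specimen_id character scalar identifying the specimen.
#' @param sex,batch optional character scalars recorded as metadata.
#' @param landmarks optional named list of length-3 numeric vectors giving
#'   landmark coordinates (same units and frame as `points`).
#' @return an object of class `centreline`.
#' @export
centreline <- function(points, specimen_id = "specimen", sex = NA_character_,
                       batch = NA_character_, landmarks = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 3L) stopf("centreline points must have 3 columns, got %d", ncol(points))
  if (nrow(points) < 4L) stopf("a centreline needs at least 4 points, got %d", nrow(points))
  if (any(!is.finite(points))) stopf("centreline points must be finite")
  seg <- row_norms(diff(points))
  if (any(seg == 0)) {
    warnf("collapsing %d duplicate consecutive point(s)", sum(seg == 0))
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    if (nrow(points) < 4L) stopf("fewer than 4 distinct points after collapsing duplicates")
  }
  if (!is.null(landmarks)) {
    if (is.null(names(landmarks)) || any(!nzchar(names(landmarks)))) {
      stopf("landmarks must be a named list")
    }
    landmarks <- lapply(landmarks, function(p) {
      p <- as.numeric(p)
      if (length(p) != 3L || any(!is.finite(p))) stopf("each landmark must be a finite 3-vector")
      p
    })
  }
  structure(list(points = points, specimen_id = as.character(specimen_id),
                 sex = as.character(sex), batch = as.character(batch),
                 landmarks = landmarks),
            class = "centreline")
}

#' @export
print.centreline <- function(x, ...) {
  cat(sprintf("centreline '%s': %d points, %.1f um long%s\n", x$specimen_id,
              nrow(x$points), sum(row_norms(diff(x$points))),
              if (length(x$landmarks)) {
                sprintf(", landmarks: %s", paste(names(x$landmarks), collapse = ", "))
              } else ""))
  invisible(x)
}

#' Read a centreline from SWC or CSV
#'
#' SWC files (the neurite-tracing dialect: columns id, type, x, y, z, radius,
#' parent) must encode a single unbranched path; the root is taken as the
#' anterior end and the radius column is ignored. CSV files need columns
#' x, y, z (header optional); rows are taken in order, first row anterior.
#' Coordinates are assumed to be in micrometres; traces recorded in voxel
#' units can be converted with `scale`.
#'
#' @param path path to the file.
#' @param format `"swc"` or `"csv"`; defaults to the file extension.
#' @param scale multiplier applied to all coordinates (e.g. a voxel size in
#'   micrometres); default 1.
#' @param ... metadata passed on to [centreline()].
#' @return a [centreline()].
#' @export
read_centreline <- function(path, format = c("auto", "swc", "csv"), scale = 1, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.swc$", path, ignore.case = TRUE)) "swc" else "csv"
  }
  pts <- if (format == "swc") read_swc_points(path) else read_csv_points(path)
  centreline(pts * scale, ...)
}

read_swc_points <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stopf("no data rows in SWC file %s", path)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(vapply(fields, length, 1L) < 7L)
  if (length(bad)) stopf("malformed SWC row at line %d of %s", rows[bad[1L]], path)
  m <- matrix(NA_real_, length(fields), 7L)
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][1:7]))
    if (any(is.na(v))) stopf("non-numeric SWC row at line %d of %s", rows[i], path)
    m[i, ] <- v
  }
  id <- as.integer(m[, 1L]); parent <- as.integer(m[, 7L])
  nchild <- table(factor(parent[parent != -1L], levels = id))
  forks <- id[nchild > 1L]
  if (length(forks)) stopf("SWC path branches at node %d; centrelines must be unbranched", forks[1L])
  roots <- id[parent == -1L]
  if (length(roots) != 1L) stopf("SWC file must have exactly one root, found %d", length(roots))
  # walk root -> tip
  child_of <- setNames(id[parent != -1L], parent[parent != -1L])
  ord <- integer(length(id))
  cur <- roots; k <- 0L
  idx <- setNames(seq_along(id), id)
  while (!is.na(cur)) {
    k <- k + 1L
    if (k > length(id)) stopf("SWC parent pointers form a cycle")
    ord[k] <- idx[[as.character(cur)]]
    nxt <- child_of[as.character(cur)]
    cur <- if (is.na(nxt)) NA_integer_ else as.integer(nxt)
  }
  if (k != length(id)) stopf("SWC file contains %d disconnected node(s)", length(id) - k)
  m[ord, 3:5, drop = FALSE]
}

read_csv_points <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[-0-9eE+.,[:space:]]+$", sub("^#.*", "", first)) || grepl("[xyz]", first)
  df <- tryCatch(
    read.table(path, sep = ",", header = has_header, comment.char = "#",
               strip.white = TRUE),
    error = function(e) stopf("cannot parse CSV %s: %s", path, conditionMessage(e)))
  cols <- if (all(c("x", "y", "z") %in% names(df))) c("x", "y", "z") else 1:3
  m <- suppressWarnings({
    mm <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(mm) <- "double"  # coercion NAs reported as row errors below
    mm
  })
  if (any(!is.finite(m))) {
    stopf("non-numeric coordinate at data row %d of %s", which(!stats::complete.cases(m))[1L], path)
  }
  m
}

#' Write a centreline to SWC or CSV
#'
#' The SWC writer emits an unbranched root-to-tip path (type 0, unit radius);
#' the CSV writer emits x,y,z rows in micrometres with the metadata in a
#' header comment.
#'
#' @param x a [centreline()].
#' @param path output path.
#' @param format `"swc"` or `"csv"`.
#' @export
write_centreline <- function(x, path, format = c("csv", "swc")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "centreline"))
  p <- x$points
  if (format == "swc") {
    n <- nrow(p)
    lines <- c("# SWC centreline (unbranched), coordinates in um",
               sprintf("# specimen_id: %s", x$specimen_id),
               sprintf("%d 0 %.10g %.10g %.10g 1 %d",
                       seq_len(n), p[, 1L], p[, 2L], p[, 3L],
                       c(-1L, seq_len(n - 1L))))
    writeLines(lines, path)
  } else {
    lines <- c(sprintf("# centreline specimen_id=%s sex=%s batch=%s units=um",
                       x$specimen_id, x$sex, x$batch),
               "x,y,z",
               sprintf("%.10g,%.10g,%.10g", p[, 1L], p[, 2L], p[, 3L]))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Arclength-parameterize a centreline
#'
#' Computes the cumulative arclength coordinate s for every point by summing
#' the lengths of the line segments leading up to it from the anterior end,
#' giving s(1) = 0 and s(n) = L, the total centreline length.
#'
#' @param x a [centreline()] (or a bare n x 3 matrix).
#' @return an object of class `param_curve` with fields `points`, `s`, `L`,
#'   plus the centreline's metadata and landmarks.
#' @export
parameterize <- function(x) {
  if (inherits(x, "param_curve")) return(x)
  if (is.matrix(x)) x <- centreline(x)
  stopifnot(inherits(x, "centreline"))
  seg <- row_norms(diff(x$points))
  s <- c(0, cumsum(seg))
  structure(list(points = x$points, s = s, L = s[length(s)],
                 specimen_id = x$specimen_id, sex = x$sex, batch = x$batch,
                 landmarks = x$landmarks),
            class = "param_curve")
}

#' @export
print.param_curve <- function(x, ...) {
  cat(sprintf("param_curve '%s': %d points, L = %.2f um\n",
              x$specimen_id, nrow(x$points), x$L))
  invisible(x)
}

#' Total centreline length
#'
#' Gut length is measured as centreline length; regional lengths are obtained
#' by subsetting with [subset_by_landmarks()] first.
#'
#' @param p a `param_curve` (or anything [parameterize()] accepts).
#' @return length in micrometres.
#' @export
curve_length <- function(p) parameterize(p)$L

# Index of the curve point nearest to a named landmark; errors beyond the
# snap radius because landmarks are placed on image stacks, not on the curve.
snap_landmark <- function(p, name, snap_radius) {
  if (is.null(p$landmarks) || is.null(p$landmarks[[name]])) {
    stopf("landmark '%s' not present on curve '%s'", name, p$specimen_id)
  }
  lm <- p$landmarks[[name]]
  d2 <- colSums((t(p$points) - lm)^2)
  i <- which.min(d2)
  if (sqrt(d2[i]) > snap_radius) {
    stopf("landmark '%s' is %.1f um from the curve (snap radius %.1f um)",
          name, sqrt(d2[i]), snap_radius)
  }
  i
}

#' Subset a curve between two landmarks
#'
#' Each landmark is mapped to the nearest centreline point (within
#' `snap_radius`); the contiguous sub-curve between the two mapped points is
#' returned, re-parameterized from s = 0. `from_lm` must be anterior of
#' `to_lm`.
#'
#' @param p a `param_curve` carrying landmarks.
#' @param from_lm,to_lm landmark names.
#' @param snap_radius maximum landmark-to-curve distance in micrometres
#'   (default 30, about ten image voxels).
#' @return a `param_curve` over the subregion.
#' @export
subset_by_landmarks <- function(p, from_lm, to_lm, snap_radius = 30) {
  p <- parameterize(p)
  i <- snap_landmark(p, from_lm, snap_radius)
  j <- snap_landmark(p, to_lm, snap_radius)
  if (j <= i) stopf("landmark '%s' (s=%.1f) is not anterior of '%s' (s=%.1f)",
                    from_lm, p$s[i], to_lm, p$s[j])
  pts <- p$points[i:j, , drop = FALSE]
  s <- p$s[i:j] - p$s[i]
  structure(list(points = pts, s = s, L = s[length(s)],
                 specimen_id = p$specimen_id, sex = p$sex, batch = p$batch,
                 landmarks = p$landmarks),
            class = "param_curve")
}

#' Resample a curve to equally spaced pseudolandmarks
#'
#' Places `k` points at arclengths j*L/(k-1), j = 0..k-1, linearly
#' interpolated along the polyline, so that curves become comparable
#' landmark-wise (1000 pseudolandmarks for whole guts, 500 for the midgut
#' loop region, by convention).
#'
#' @param p a `param_curve`.
#' @param k number of pseudolandmarks (>= 2).
#' @param max_k guard against accidental huge requests.
#' @return a k x 3 matrix of class `landmark_config` with the specimen id in
#'   attribute `specimen_id`.
#' @export
resample_equal <- function(p, k, max_k = 100000L) {
  p <- parameterize(p)
  if (!is_count(k) || k < 2L) stopf("k must be an integer >= 2")
  if (k > max_k) stopf("k = %d exceeds the configured maximum %d", k, max_k)
  # refine: re-measure the chordal arclength of the resampled polyline and
  # resample again, so consecutive spacings equalize to float tolerance
  # (a single pass leaves small deficits where the polyline bends)
  s_cur <- p$s
  m <- p$points
  for (pass in 1:12) {
    s_out <- seq(0, s_cur[length(s_cur)], length.out = k)
    m <- interp_cols(s_cur, m, s_out)
    sp <- row_norms(diff(m))
    if (max(sp) / min(sp) < 1 + 1e-9) break
    s_cur <- c(0, cumsum(sp))
  }
  m[1L, ] <- p$points[1L, ]
  m[k, ] <- p$points[nrow(p$points), ]
  structure(m, class = c("landmark_config", "matrix", "array"),
            specimen_id = p$specimen_id, s = s_out, L = p$L)
}

#' Resample a curve to an equally spaced param_curve
#'
#' Same placement rule as [resample_equal()] but returning a `param_curve`,
#' convenient for downstream profile estimation on a uniform grid.
#'
#' @inheritParams resample_equal
#' @return a `param_curve` with `k` points.
#' @export
resample_curve <- function(p, k) {
  p <- parameterize(p)
  m <- resample_equal(p, k)
  q <- parameterize(centreline(unclass(m)[, , drop = FALSE],
                               specimen_id = p$specimen_id, sex = p$sex,
                               batch = p$batch, landmarks = p$landmarks))
  q
}

#' Write a cohort of centrelines and metadata to a directory
#'
#' Serializes each centreline as CSV plus a single cohort metadata table
#' keyed by `specimen_id`.
#'
#' @param cohort list with elements `centreline` and `meta` (one-row data
#'   frame), as produced by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the metadata table that was written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(cohort, `[[`, "meta"))
  for (sp in cohort) {
    write_centreline(sp$centreline,
                     file.path(dir, paste0(sp$centreline$specimen_id, ".csv")))
  }
  write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(meta)
}
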