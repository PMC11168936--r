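#' Construct a scalar profile
#'
#' A scalar function of arclength: curvature (1/um), torsion (1/um),
#' normalized curvature (dimensionless), radius (um) or intensity (arbitrary
#' units), sampled at increasing arclengths.
#'
#' @param s arclength samples (micrometres, or fraction of L if `relative`).
#' @param values one value per sample; may contain NA where flagged undefined.
#' @param kind one of `"curvature"`, `"torsion"`, `"normalized_curvature"`,
#'   `"radius"`, `"intensity"`.
#' @param L total curve length in micrometres (kept for normalization).
#' @param specimen_id optional identifier.
#' @param anchor optional anchor position as a fraction of length (used by
#'   intensity profiles to mark the R3 landmark).
#' @return an object of class `scalar_profile`.
#' @export
scalar_profile <- function(s, values,
                           kind = c("intensity", "curvature", "torsion",
                                    "normalized_curvature", "radius"),
                           L = NULL, specimen_id = "", anchor = NA_real_) {
  kind <- match.arg(kind)
  s <- as.numeric(s); values <- as.numeric(values)
  if (length(s) != length(values)) stopf("s and values must have equal length")
  if (any(diff(s) <= 0)) stopf("s must be strictly increasing")
  structure(list(s = s, values = values, kind = kind,
                 L = if (is.null(L)) s[length(s)] - s[1L] else L,
                 specimen_id = specimen_id, anchor = anchor),
            class = "scalar_profile")
}

#' @export
print.scalar_profile <- function(x, ...) {
  cat(sprintf("scalar_profile [%s] '%s': %d samples on [%.3g, %.3g], %d undefined\n",
              x$kind, x$specimen_id, length(x$s), x$s[1L], x$s[length(x$s)],
              sum(is.na(x$values))))
  invisible(x)
}

#' Export profiles as a tidy table
#'
#' @param profiles a `scalar_profile` or list thereof.
#' @return data frame with columns specimen_id, s, s_over_L, kind, value,
#'   undefined_flag.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "scalar_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(f) {
    span <- f$s[length(f$s)] - f$s[1L]
    data.frame(specimen_id = f$specimen_id, s = f$s,
               s_over_L = (f$s - f$s[1L]) / ifelse(span > 0, span, 1),
               kind = f$kind, value = f$values,
               undefined_flag = is.na(f$values))
  }))
}

## ---- zero-phase low-pass filtering -----------------------------------------

# Steady-state initial filter delays for a direct-form-II-transposed IIR
# filter (b, a), such that filtering a constant input reproduces it exactly.
lfilter_zi <- function(b, a) {
  a <- a / a[1L]; b <- b / a[1L]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  comp <- rbind(-a[-1L], cbind(diag(n - 2L), 0))
  IminusA <- diag(n - 1L) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

iir_filter <- function(b, a, x, zi) {
  n <- length(x); m <- length(zi)
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    y[i] <- b[1L] * x[i] + z[1L]
    if (m > 1L) {
      z[-m] <- b[2:m] * x[i] + z[-1L] - a[2:m] * y[i]
    }
    z[m] <- b[m + 1L] * x[i] - a[m + 1L] * y[i]
  }
  y
}

# Zero-phase Butterworth filtering with odd-reflection padding and
# steady-state initial conditions (constant signals pass unchanged).
filtfilt_pad <- function(b, a, x) {
  nf <- max(length(a), length(b))
  pad <- 3L * (nf - 1L) * 2L
  n <- length(x)
  if (n <= nf * 3L) return(x)
  pad <- min(pad, n - 1L)
  front <- 2 * x[1L] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xx <- c(front, x, back)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xx, zi * xx[1L])
  y <- rev(y)
  y <- iir_filter(b, a, y, zi * y[1L])
  y <- rev(y)
  y[(pad + 1L):(pad + n)]
}

#' Low-pass smooth a profile
#'
#' Zero-phase (forward-backward) 4th-order Butterworth low-pass filter with
#' normalized cutoff expressed as a fraction of the Nyquist frequency.
#' Values are resampled to a uniform grid internally if needed and NA runs
#' are linearly interpolated before filtering (and restored after).
#'
#' @param f a [scalar_profile()].
#' @param cutoff normalized cutoff in (0, 1); default 0.3.
#' @param order filter order; default 4.
#' @return a smoothed `scalar_profile` on the same sample grid.
#' @export
smooth_profile <- function(f, cutoff = 0.3, order = 4L) {
  stopifnot(inherits(f, "scalar_profile"))
  if (cutoff <= 0 || cutoff >= 1) stopf("cutoff must be in (0, 1)")
  v <- f$values
  n <- length(v)
  if (n <= (order + 1L) * 3L) {
    warnf("profile has too few samples (%d) for the order-%d filter; returned unfiltered", n, order)
    return(f)
  }
  nas <- is.na(v)
  if (all(nas)) return(f)
  if (any(nas)) {
    v <- approx(f$s[!nas], v[!nas], f$s, rule = 2, ties = "ordered")$y
  }
  ds <- diff(f$s)
  uniform <- diff(range(ds)) <= 1e-8 * mean(ds)
  su <- if (uniform) f$s else seq(f$s[1L], f$s[n], length.out = n)
  vu <- if (uniform) v else approx(f$s, v, su, ties = "ordered")$y
  bw <- signal::butter(order, cutoff)
  sm <- filtfilt_pad(bw$b, bw$a, vu)
  out <- if (uniform) sm else approx(su, sm, f$s, ties = "ordered")$y
  out[nas] <- NA_real_
  g <- f
  g$values <- out
  g
}

## ---- local Taylor fits and Frenet-Serret descriptors -----------------------

#' Local cubic (third-degree Taylor) fit of a curve
#'
#' Fits each coordinate of the curve, within the neighbourhood
#' \{points with |s - s*| < delta\}, to an unweighted least-squares cubic in
#' (s - s*). The derivatives at s* are read off the fitted coefficients
#' (x' = linear, x'' = 2 x quadratic, x''' = 6 x cubic). Neighbourhoods are
#' truncated (asymmetric) at the curve ends.
#'
#' @param p a `param_curve`.
#' @param s_star evaluation arclength (micrometres).
#' @param delta neighbourhood half-width (micrometres); conventionally
#'   0.05 * L.
#' @return list with `s_star`, `d1`, `d2`, `d3` (length-3 derivative vectors)
#'   and `n_neighbors`.
#' @export
local_cubic_fit <- function(p, s_star, delta) {
  p <- parameterize(p)
  idx <- which(abs(p$s - s_star) < delta)
  if (length(idx) < 4L) {
    stopf("only %d point(s) within delta = %.3g of s* = %.3g; resample the curve more densely or increase delta",
          length(idx), delta, s_star)
  }
  u <- p$s[idx] - s_star
  X <- cbind(1, u, u^2, u^3)
  fit <- lm.fit(X, p$points[idx, , drop = FALSE])
  cf <- fit$coefficients
  list(s_star = s_star,
       d1 = cf[2L, ],
       d2 = 2 * cf[3L, ],
       d3 = 6 * cf[4L, ],
       n_neighbors = length(idx))
}

#' Curvature and torsion along a curve
#'
#' Arclength-parameterizes the curve, resamples it to `n_eval` equally
#' spaced points, Taylor-fits a cubic in a neighbourhood of size
#' `delta_frac * L` around every point, and applies the Frenet-Serret
#' relations kappa = |x''| and tau = ((x' x x'') . x''') / kappa^2. Both
#' profiles are then smoothed with [smooth_profile()]. Where kappa falls
#' below `kappa_eps` the torsion is recorded as undefined (NA), since the
#' formula divides by kappa^2.
#'
#' @param p a `param_curve` (or anything [parameterize()] accepts).
#' @param delta_frac neighbourhood size as a fraction of total length;
#'   default 0.05.
#' @param n_eval number of equally spaced evaluation points (default 1000);
#'   `NULL` evaluates at the curve's own points.
#' @param cutoff smoothing cutoff passed to [smooth_profile()]; `NULL` skips
#'   smoothing.
#' @param kappa_eps curvature floor below which torsion is undefined.
#' @return list with `curvature` and `torsion` [scalar_profile()]s.
#' @export
curvature_torsion <- function(p, delta_frac = 0.05, n_eval = 1000L,
                              cutoff = 0.3, kappa_eps = 1e-6) {
  p <- parameterize(p)
  if (delta_frac <= 0 || delta_frac >= 0.5) stopf("delta_frac must be in (0, 0.5)")
  if (!is.null(n_eval)) p <- resample_curve(p, n_eval)
  n <- nrow(p$points)
  if (n < 4L) stopf("need at least 4 points")
  delta <- delta_frac * p$L
  kap <- numeric(n); tor <- numeric(n)
  s <- p$s; pts <- p$points
  for (i in seq_len(n)) {
    lo <- findInterval(s[i] - delta, s) + 1L
    hi <- findInterval(s[i] + delta - 1e-12 * p$L, s)
    idx <- lo:hi
    if (length(idx) < 4L) {
      stopf("only %d point(s) within delta at s* = %.3g; resample the curve more densely or increase delta_frac",
            length(idx), s[i])
    }
    u <- s[idx] - s[i]
    X <- cbind(1, u, u * u, u * u * u)
    cf <- lm.fit(X, pts[idx, , drop = FALSE])$coefficients
    d1 <- cf[2L, ]; d2 <- 2 * cf[3L, ]; d3 <- 6 * cf[4L, ]
    k <- sqrt(sum(d2 * d2))
    kap[i] <- k
    tor[i] <- if (k < kappa_eps) NA_real_ else sum(vcross(d1, d2) * d3) / (k * k)
  }
  fk <- scalar_profile(s, kap, "curvature", L = p$L, specimen_id = p$specimen_id)
  ft <- scalar_profile(s, tor, "torsion", L = p$L, specimen_id = p$specimen_id)
  if (!is.null(cutoff)) {
    fk <- smooth_profile(fk, cutoff)
    fk$values <- pmax(fk$values, 0)  # curvature is non-negative by definition
    ft <- smooth_profile(ft, cutoff)
  }
  list(curvature = fk, torsion = ft)
}

#' Normalize curvature or torsion by total length
#'
#' Curvature and torsion have units of inverse length; multiplying by the
#' total centreline length L gives scale-invariant shape descriptors
#' (normalized curvature and torsion). A circle of any radius has normalized
#' curvature 2*pi.
#'
#' @param f a curvature or torsion [scalar_profile()].
#' @param L total length (micrometres); defaults to the length stored on the
#'   profile.
#' @return a dimensionless `scalar_profile`.
#' @export
normalize_by_length <- function(f, L = NULL) {
  stopifnot(inherits(f, "scalar_profile"))
  if (!f$kind %in% c("curvature", "torsion")) {
    stopf("normalize_by_length applies to curvature or torsion profiles, not '%s'", f$kind)
  }
  if (is.null(L)) L <- f$L
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) stopf("L must be positive")
  g <- f
  g$values <- f$values * L
  g$kind <- "normalized_curvature"
  g
}

#' Radius profile from a surface mesh
#'
#' Estimates the local tube radius at every centreline point as the minimum
#' distance to the vertices of the organ's (unsmoothed) surface mesh, then
#' low-pass smooths the result along arclength. The vertex-based distance
#' carries a bias of about half the mesh edge length.
#'
#' @param p a `param_curve` inside the mesh.
#' @param mesh a [surface_mesh()].
#' @param cutoff smoothing cutoff (fraction of Nyquist); default 0.3.
#' @return a radius [scalar_profile()] (micrometres).
#' @export
radius_profile <- function(p, mesh, cutoff = 0.3) {
  p <- parameterize(p)
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$vertices) == 0L) stopf("mesh has no vertices")
  bb_lo <- apply(mesh$vertices, 2L, min); bb_hi <- apply(mesh$vertices, 2L, max)
  outside <- apply(p$points, 1L, function(x) any(x < bb_lo | x > bb_hi))
  if (any(outside)) {
    warnf("%d centreline point(s) fall outside the mesh bounding box", sum(outside))
  }
  d <- nearest_distance(p$points, mesh$vertices)
  f <- scalar_profile(p$s, d, "radius", L = p$L, specimen_id = p$specimen_id)
  if (!is.null(cutoff)) f <- smooth_profile(f, cutoff)
  f
}

#' Tilt of a subregion relative to the whole organ
#'
#' The main axis of a point set is the leading eigendirection of its 3x3
#' covariance matrix. The tilt is the angle between the main axis of the
#' whole curve (V_g) and that of the subregion (V_m), computed as
#' arccos(|V_g . V_m|) on unit eigenvectors and reported in degrees within
#' \[0, 90\]; the absolute value resolves the eigenvector sign ambiguity.
#'
#' @param whole a `param_curve` (whole organ).
#' @param subregion a `param_curve` (e.g. the midgut loop region).
#' @return angle in degrees.
#' @export
tilt_angle <- function(whole, subregion) {
  v1 <- main_axis(parameterize(whole)$points)
  v2 <- main_axis(parameterize(subregion)$points)
  ang <- acos(min(1, abs(sum(v1 * v2))))
  ang * 180 / pi
}

main_axis <- function(pts) {
  if (nrow(pts) < 3L) stopf("need at least 3 points for a main axis")
  e <- eigen(cov(pts), symmetric = TRUE)
  if ((e$values[1L] - e$values[2L]) <= 1e-8 * max(e$values[1L], 1e-300)) {
    stopf("leading eigendirection is degenerate (isotropic point cloud)")
  }
  unit(e$vectors[, 1L])
}
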