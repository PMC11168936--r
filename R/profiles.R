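# Arclength intensity profiles: R3-anchored binning, unit normalization,
# all-pairs registered correlation with curvature, and the autoregressive
# null model.

#' Align traces at their anchor and bin along gut length
#'
#' Each trace's positions are rescaled piecewise-linearly so its anchor (the
#' R3 landmark) maps to 50% of gut length and the ends to 0% and 100%,
#' making positions comparable across specimens and sexes. Values are then
#' binned into `n_bins` equal-width bins (left-closed, right-open, final bin
#' closed): each specimen contributes its per-bin mean, and the output
#' reports the across-specimen mean and standard deviation per bin.
#'
#' @param traces list of intensity [scalar_profile()]s, each carrying an
#'   `anchor` fraction strictly inside (0, 1).
#' @param n_bins number of bins (default 40).
#' @return an object of class `binned_profile`: data frame with columns
#'   `bin`, `mid` (bin midpoint as fraction of length), `mean`, `sd`, `n`;
#'   anchor position (0.5) in attribute `anchor`.
#' @export
align_and_bin <- function(traces, n_bins = 40L) {
  if (inherits(traces, "scalar_profile")) traces <- list(traces)
  if (!length(traces)) stopf("no traces supplied")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  per_spec <- matrix(NA_real_, length(traces), n_bins)
  for (i in seq_along(traces)) {
    f <- traces[[i]]
    stopifnot(inherits(f, "scalar_profile"))
    a <- f$anchor
    if (is.na(a)) stopf("trace '%s' has no anchor position", f$specimen_id)
    if (a <= 0 || a >= 1) stopf("anchor at %.3g is degenerate; must be inside (0, 1)", a)
    span <- f$s[length(f$s)] - f$s[1L]
    u <- (f$s - f$s[1L]) / span
    pos <- ifelse(u <= a, u * 0.5 / a, 0.5 + (u - a) * 0.5 / (1 - a))
    bin <- findInterval(pos, edges, rightmost.closed = TRUE, all.inside = TRUE)
    ok <- !is.na(f$values)
    per_spec[i, ] <- vapply(seq_len(n_bins), function(b) {
      v <- f$values[ok & bin == b]
      if (length(v)) mean(v) else NA_real_
    }, 1)
  }
  structure(data.frame(
    bin = seq_len(n_bins),
    mid = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
    mean = apply(per_spec, 2L, function(v) mean(v, na.rm = TRUE)),
    sd = apply(per_spec, 2L, function(v) if (sum(!is.na(v)) > 1L) sd(v, na.rm = TRUE) else 0),
    n = apply(per_spec, 2L, function(v) sum(!is.na(v)))),
    anchor = 0.5, per_specimen = per_spec,
    class = c("binned_profile", "data.frame"))
}

#' Unit-normalize a profile
#'
#' Maps values affinely so the minimum becomes 0 and the maximum 1,
#' I_tilde = (I - min I) / (max I - min I), allowing comparison across
#' specimens with different staining or curvature scales. (Pearson
#' correlations are unaffected by the affine choice of range.)
#'
#' @param f a [scalar_profile()] with non-zero range.
#' @return a `scalar_profile` with values in \[0, 1\].
#' @export
unit_normalize <- function(f) {
  stopifnot(inherits(f, "scalar_profile"))
  v <- f$values
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1L]) || rng[2L] <= rng[1L]) {
    stopf("profile '%s' is constant; unit normalization undefined", f$specimen_id)
  }
  g <- f
  g$values <- (v - rng[1L]) / (rng[2L] - rng[1L])
  g
}

#' All-pairs registered correlation of curvature and intensity profiles
#'
#' Pairs every curvature profile with every intensity profile (analyse the
#' sexes separately by calling once per sex), elastically registers the
#' intensity curve onto the curvature curve, and computes the Pearson
#' correlation coefficient on the registered common grid, giving
#' n_curvature x n_intensity coefficients.
#'
#' @param curvatures list of (unit-normalized) curvature [scalar_profile()]s.
#' @param intensities list of (unit-normalized) intensity profiles.
#' @param n_grid registration/evaluation grid size (default 101).
#' @return an object of class `correlation_set`: list with `coefficients`
#'   (n_curvature x n_intensity matrix of Pearson r) and `provenance`
#'   (data frame of id pairs per cell).
#' @export
pairwise_profile_correlation <- function(curvatures, intensities, n_grid = 101L) {
  if (!length(curvatures)) stopf("empty curvature list")
  if (!length(intensities)) stopf("empty intensity list")
  nc <- length(curvatures); ni <- length(intensities)
  grid_eval <- seq(0, 1, length.out = n_grid)
  vc <- lapply(curvatures, profile_on_unit_grid, n = n_grid)
  vi <- lapply(intensities, profile_on_unit_grid, n = n_grid)
  qc <- lapply(vc, srsf)
  qi <- lapply(vi, srsf)
  r <- matrix(NA_real_, nc, ni)
  for (i in seq_len(nc)) {
    for (j in seq_len(ni)) {
      g <- .dp_warp(qc[[i]], qi[[j]])
      warped <- approx(grid_eval, vi[[j]], pmin(pmax(g, 0), 1),
                       rule = 2, ties = "ordered")$y
      r[i, j] <- if (sd(vc[[i]]) == 0 || sd(warped) == 0) NA_real_ else cor(vc[[i]], warped)
    }
  }
  ids_c <- vapply(curvatures, function(f) f$specimen_id, character(1L))
  ids_i <- vapply(intensities, function(f) f$specimen_id, character(1L))
  prov <- expand.grid(curvature_id = ids_c, intensity_id = ids_i,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(list(coefficients = r, provenance = prov,
                 n_curvature = nc, n_intensity = ni),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  r <- x$coefficients
  cat(sprintf("correlation_set: %d x %d = %d coefficients, median r = %.3f\n",
              x$n_curvature, x$n_intensity, length(r), median(r, na.rm = TRUE)))
  invisible(x)
}

# Fit an AR(p) model to a trace by ordinary least squares, falling back to
# Yule-Walker when OLS fails or is non-stationary.
fit_ar <- function(x, order) {
  if (order >= length(x)) stopf("AR order %d >= trace length %d", order, length(x))
  fit <- tryCatch(ar(x, aic = FALSE, order.max = order, method = "ols", demean = TRUE),
                  error = function(e) NULL)
  phi <- if (!is.null(fit)) as.numeric(fit$ar) else numeric(0)
  if (!length(phi) || !ar_stationary(phi)) {
    fit <- ar(x, aic = FALSE, order.max = order, method = "yule-walker", demean = TRUE)
    phi <- as.numeric(fit$ar)
  }
  list(phi = phi, innov_var = max(fit$var.pred, 1e-12, na.rm = TRUE), mean = mean(x))
}

# Stationarity: all roots of 1 - phi_1 z - ... - phi_p z^p outside the unit
# circle.
ar_stationary <- function(phi) {
  if (!length(phi)) return(TRUE)
  all(Mod(polyroot(c(1, -phi))) > 1)
}

#' Autoregressive null for curvature-intensity correlations
#'
#' Fits an AR(`order`) process to each observed intensity trace, simulates
#' `n_sim` surrogate traces per fit, and recomputes the all-pairs registered
#' correlations of the observed curvature profiles against the surrogates,
#' exactly as in [pairwise_profile_correlation()]. The resulting null
#' distribution shows what correlation magnitudes arise from the
#' autocorrelation structure of the intensity signal alone.
#'
#' @param intensities list of observed intensity [scalar_profile()]s.
#' @param curvatures list of curvature profiles the null is computed
#'   against; `NULL` skips the correlation step.
#' @param n_sim surrogates per observed trace (0 gives an empty null set).
#' @param order AR order (default 1).
#' @param seed simulation seed.
#' @param n_grid grid passed to the correlation step.
#' @return list with `fits` (per-trace coefficients, innovation variance,
#'   mean), `simulated` (list of surrogate `scalar_profile`s) and
#'   `null_correlations` (a `correlation_set`, or NULL).
#' @export
ar_null <- function(intensities, curvatures = NULL, n_sim = 10L, order = 1L,
                    seed = 1L, n_grid = 101L) {
  if (!length(intensities)) stopf("empty intensity list")
  fits <- lapply(intensities, function(f) fit_ar(f$values, order))
  sims <- list()
  if (n_sim > 0L) {
    sims <- with_seed(seed, {
      out <- list()
      for (i in seq_along(intensities)) {
        f <- intensities[[i]]
        ft <- fits[[i]]
        for (r in seq_len(n_sim)) {
          v <- as.numeric(arima.sim(model = if (length(ft$phi)) list(ar = ft$phi) else list(),
                                    n = length(f$values),
                                    sd = sqrt(ft$innov_var))) + ft$mean
          out[[length(out) + 1L]] <- scalar_profile(
            f$s, v, "intensity", L = f$L,
            specimen_id = sprintf("%s_sim%d", f$specimen_id, r),
            anchor = f$anchor)
        }
      }
      out
    })
  }
  nullcor <- NULL
  if (!is.null(curvatures) && length(sims)) {
    sims_norm <- lapply(sims, function(f) {
      tryCatch(unit_normalize(f), error = function(e) f)
    })
    nullcor <- pairwise_profile_correlation(curvatures, sims_norm, n_grid = n_grid)
  }
  list(fits = fits, simulated = sims, null_correlations = nullcor)
}

#' Correlation of binned curvature and intensity profiles
#'
#' Pearson product-moment correlation of the two binned mean vectors (e.g.
#' average curvature vs average tracheal intensity along the midgut).
#'
#' @param binned_curvature,binned_intensity [align_and_bin()] outputs with
#'   equal bin counts.
#' @return Pearson r.
#' @export
curvature_intensity_correlation <- function(binned_curvature, binned_intensity) {
  a <- binned_curvature$mean; b <- binned_intensity$mean
  if (length(a) != length(b)) stopf("bin counts differ (%d vs %d)", length(a), length(b))
  ok <- is.finite(a) & is.finite(b)
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) stopf("zero-variance binned vector")
  cor(a[ok], b[ok])
}

#' Export a correlation set as a tidy table
#'
#' @param cs a `correlation_set`.
#' @return data frame (curvature_id, intensity_id, r).
#' @export
correlation_table <- function(cs) {
  stopifnot(inherits(cs, "correlation_set"))
  cbind(cs$provenance, r = as.numeric(cs$coefficients))
}
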