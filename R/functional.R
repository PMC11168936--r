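# Cross-specimen comparison of curvature functions: elastic registration,
# the discretized curvature distance, MDS embedding, confidence ellipsoids
# and group location tests.

# Resample a profile onto `n` uniform points of relative arclength in [0,1].
profile_on_unit_grid <- function(f, n) {
  stopifnot(inherits(f, "scalar_profile"))
  v <- f$values
  nas <- is.na(v)
  if (any(nas)) {
    if (mean(nas) >= 0.05) {
      stopf("profile '%s' has %.0f%% undefined samples (max 5%% interpolated over)",
            f$specimen_id, 100 * mean(nas))
    }
    v <- approx(f$s[!nas], v[!nas], f$s, rule = 2, ties = "ordered")$y
  }
  span <- f$s[length(f$s)] - f$s[1L]
  if (span <= 0) stopf("profile has zero arclength span")
  u <- (f$s - f$s[1L]) / span
  approx(u, v, seq(0, 1, length.out = n), rule = 2, ties = "ordered")$y
}

srsf <- function(v) {
  n <- length(v)
  du <- 1 / (n - 1)
  g <- c(v[2L] - v[1L], (v[3L:n] - v[1L:(n - 2L)]) / 2, v[n] - v[n - 1L]) / du
  sign(g) * sqrt(abs(g))
}

#' Elastic registration of two profiles
#'
#' Finds the boundary-anchored monotone warping s2 = gamma(s1) that
#' minimizes the Fisher-Rao (square-root-slope) misalignment between the two
#' profiles by dynamic programming on a uniform grid of relative arclength.
#' Profiles of different physical lengths are compared on s/L in \[0, 1\].
#' When both profiles are constant every warping is optimal and the identity
#' is returned (tie-break).
#'
#' @param f1,f2 [scalar_profile()]s with at least 10 samples each.
#' @param n_grid grid resolution for the dynamic program (default 101).
#' @return an object of class `warping`: list with `grid` (s1/L1 values),
#'   `gamma` (s2/L2 values) and `n_grid`.
#' @export
elastic_register <- function(f1, f2, n_grid = 101L) {
  if (length(f1$s) < 10L || length(f2$s) < 10L) {
    stopf("profiles need at least 10 samples for elastic registration")
  }
  v1 <- profile_on_unit_grid(f1, n_grid)
  v2 <- profile_on_unit_grid(f2, n_grid)
  g <- .dp_warp(srsf(v1), srsf(v2))
  structure(list(grid = seq(0, 1, length.out = n_grid), gamma = g,
                 n_grid = n_grid),
            class = "warping")
}

#' @export
print.warping <- function(x, ...) {
  cat(sprintf("warping on %d grid points, max |gamma - id| = %.4f\n",
              x$n_grid, max(abs(x$gamma - x$grid))))
  invisible(x)
}

warp_eval <- function(w, s) approx(w$grid, w$gamma, s, rule = 2, ties = "ordered")$y

# One-directional registered RMS difference on n equally spaced s1 points.
registered_rms <- function(v1, v2, gamma, grid_eval) {
  n_grid <- length(v1)
  u <- seq(0, 1, length.out = n_grid)
  g_eval <- approx(u, gamma, grid_eval, rule = 2, ties = "ordered")$y
  a <- approx(u, v1, grid_eval, rule = 2, ties = "ordered")$y
  b <- approx(u, v2, g_eval, rule = 2, ties = "ordered")$y
  sqrt(mean((a - b)^2))
}

#' Curvature distance between two specimens
#'
#' Registers each normalized-curvature profile onto the other elastically
#' and evaluates the discretized distance
#' sqrt((1/n) * sum_n (k1(s_n) - k2(gamma(s_n)))^2) on `n_grid` equally
#' spaced s1 points. The one-directional formula is not symmetric in its
#' arguments, so both directions are computed and averaged; if registration
#' fails to improve on the unwarped comparison the identity warping is used
#' for that direction.
#'
#' @param k1,k2 normalized-curvature [scalar_profile()]s (dimensionless).
#' @param n_grid number of discretization points (default 200).
#' @return non-negative distance.
#' @export
curvature_distance <- function(k1, k2, n_grid = 200L) {
  for (f in list(k1, k2)) {
    if (!f$kind %in% c("normalized_curvature", "intensity")) {
      stopf("curvature_distance expects dimensionless (length-normalized) profiles, got '%s'", f$kind)
    }
  }
  v1 <- profile_on_unit_grid(k1, n_grid)
  v2 <- profile_on_unit_grid(k2, n_grid)
  grid_eval <- seq(0, 1, length.out = n_grid)
  one_way <- function(a, b) {
    g <- .dp_warp(srsf(a), srsf(b))
    d_reg <- registered_rms(a, b, g, grid_eval)
    d_id <- sqrt(mean((a - b)^2))
    min(d_reg, d_id)
  }
  (one_way(v1, v2) + one_way(v2, v1)) / 2
}

#' Pairwise curvature distance matrix
#'
#' All pairwise [curvature_distance()]s across a cohort; with
#' `relative = TRUE` every distance is divided by the maximum distance over
#' all pairs in the analysis, so the largest entry is 1.
#'
#' @param profiles list of normalized-curvature [scalar_profile()]s.
#' @param relative divide by the maximum pairwise distance?
#' @param n_grid discretization passed to [curvature_distance()].
#' @return symmetric matrix of class `distance_matrix` with specimen ids as
#'   dimnames and the `relative` flag as an attribute.
#' @export
distance_matrix <- function(profiles, relative = FALSE, n_grid = 200L) {
  n <- length(profiles)
  if (n < 2L) stopf("need at least 2 profiles")
  ids <- vapply(seq_len(n), function(i) {
    id <- profiles[[i]]$specimen_id
    if (nzchar(id)) id else sprintf("specimen_%d", i)
  }, character(1L))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- tryCatch(curvature_distance(profiles[[i]], profiles[[j]], n_grid),
                      error = function(e) {
                        stopf("distance failed for pair (%s, %s): %s",
                              ids[i], ids[j], conditionMessage(e))
                      })
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (relative) {
    mx <- max(d)
    if (mx > 0) d <- d / mx
  }
  structure(d, relative = relative, class = c("distance_matrix", "matrix", "array"))
}

#' Metric multidimensional scaling
#'
#' Embeds specimens into `dim` coordinates (mu1, mu2, mu3 by default) whose
#' pairwise Euclidean distances approximate the input distances. Classical
#' scaling (principal coordinates) provides the initial configuration, which
#' is refined by SMACOF majorization (guaranteed non-increasing stress);
#' seeded random restarts guard against local minima and the best solution
#' is returned.
#'
#' @param d symmetric distance matrix (e.g. from [distance_matrix()]).
#' @param dim embedding dimension (default 3); must be < number of items.
#' @param seed integer seed for the random restarts.
#' @param n_restarts number of random restarts in addition to the classical
#'   start (default 4).
#' @param max_iter,tol SMACOF iteration controls.
#' @return list with `points` (n x dim matrix), `stress` (Kruskal stress-1),
#'   `stress_path` (per-iteration raw stress of the winning start).
#' @export
mds_embed <- function(d, dim = 3L, seed = 1L, n_restarts = 4L,
                      max_iter = 500L, tol = 1e-12) {
  d <- unclass(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stopf("distance matrix must be symmetric")
  n <- nrow(d)
  if (n <= dim) stopf("need more items (%d) than embedding dimensions (%d)", n, dim)
  ids <- rownames(d)
  smacof <- function(X) {
    path <- numeric(0)
    s_old <- Inf
    for (it in seq_len(max_iter)) {
      dx <- as.matrix(stats::dist(X))
      s_raw <- sum((d[upper.tri(d)] - dx[upper.tri(dx)])^2)
      path <- c(path, s_raw)
      if (s_old - s_raw < tol * max(s_old, 1e-300)) break
      s_old <- s_raw
      B <- ifelse(dx > 0, -d / pmax(dx, 1e-300), 0)
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- (B %*% X) / n
    }
    list(X = X, raw = path[length(path)], path = path)
  }
  X0 <- cmdscale(d, k = dim)
  if (ncol(X0) < dim) X0 <- cbind(X0, matrix(0, n, dim - ncol(X0)))
  starts <- c(list(X0), with_seed(seed, replicate(n_restarts, {
    matrix(rnorm(n * dim, sd = max(d) / 2 + 1e-12), n, dim)
  }, simplify = FALSE)))
  fits <- lapply(starts, smacof)
  best <- fits[[which.min(vapply(fits, `[[`, 1, "raw"))]]
  denom <- sum(d[upper.tri(d)]^2)
  X <- sweep(best$X, 2L, colMeans(best$X))
  rownames(X) <- ids
  colnames(X) <- paste0("mu", seq_len(dim))
  list(points = X,
       stress = if (denom > 0) sqrt(best$raw / denom) else 0,
       stress_path = best$path)
}

#' Gaussian confidence ellipsoid of a point group
#'
#' Fits a multivariate normal to the points and returns the ellipsoid
#' containing the stated probability mass: centre at the mean, axes along
#' the covariance eigenvectors, radii sqrt(lambda_i * chi^2_d(level)).
#'
#' @param coords n x d matrix of coordinates (n >= 4).
#' @param level coverage level (default 0.95).
#' @return list with `centre`, `axes` (columns = unit axes), `radii` and
#'   `level`; also usable with [ellipsoid_contains()].
#' @export
group_ellipsoid <- function(coords, level = 0.95) {
  coords <- as.matrix(coords)
  n <- nrow(coords); d <- ncol(coords)
  if (n < 4L) stopf("need at least 4 points to fit an ellipsoid")
  S <- cov(coords)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values)) {
    stopf("singular covariance; reduce the embedding dimension or add specimens")
  }
  q <- qchisq(level, df = d)
  list(centre = colMeans(coords), axes = e$vectors,
       radii = sqrt(e$values * q), level = level, cov = S, chi2 = q)
}

#' Test whether points fall inside an ellipsoid
#'
#' @param ell an ellipsoid from [group_ellipsoid()].
#' @param coords points to test (n x d).
#' @return logical vector.
#' @export
ellipsoid_contains <- function(ell, coords) {
  coords <- as.matrix(coords)
  centred <- sweep(coords, 2L, ell$centre)
  m2 <- rowSums((centred %*% solve(ell$cov)) * centred)
  m2 <= ell$chi2
}

#' Location test between two groups of embedding coordinates
#'
#' Tests whether two groups differ in location. For univariate data a small
#' battery is consulted: if both groups pass a Shapiro-Wilk normality check
#' (at `alpha_normality`) a Welch two-sample t test (or its paired variant)
#' is used, otherwise the Mann-Whitney U test (or Wilcoxon signed-rank when
#' paired). For multivariate data with normality accepted per coordinate,
#' Hotelling's T-squared test is used; otherwise a permutation test on the
#' distance between group centroids. The test is chosen by applicability
#' checks, never by taking the smallest p among candidates, which would
#' inflate the type I error.
#'
#' @param group_a,group_b numeric vectors or n x d coordinate matrices with
#'   matching d (>= 3 points per group).
#' @param paired treat observations as paired?
#' @param alpha_normality significance level of the normality screen.
#' @param n_perm permutations for the non-normal multivariate fallback.
#' @param seed seed for that fallback.
#' @return list with `p`, `test` (name of the selected test), `statistic`
#'   and `selection` (the logged applicability decisions).
#' @export
location_test <- function(group_a, group_b, paired = FALSE,
                          alpha_normality = 0.1, n_perm = 999L, seed = 1L) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (ncol(A) != ncol(B)) stopf("groups have unequal dimensionality (%d vs %d)", ncol(A), ncol(B))
  if (nrow(A) < 3L || nrow(B) < 3L) stopf("need at least 3 points per group")
  d <- ncol(A)
  shap_p <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3L || length(x) > 5000L) return(1)
    if (sd(x) == 0) return(1)
    shapiro.test(x)$p.value
  }
  shap_ok <- function(x) shap_p(x) >= alpha_normality
  if (d == 1L) {
    a <- A[, 1L]; b <- B[, 1L]
    normal <- shap_ok(a) && shap_ok(b)
    selection <- sprintf("univariate; normality %s at alpha=%.2g; paired=%s",
                         if (normal) "accepted" else "rejected", alpha_normality, paired)
    if (identical(a, b)) {
      return(list(p = 1, test = "identical-groups", statistic = 0, selection = selection))
    }
    if (normal) {
      tt <- t.test(a, b, paired = paired)
      return(list(p = tt$p.value, test = if (paired) "paired t-test" else "Welch t-test",
                  statistic = unname(tt$statistic), selection = selection))
    }
    wt <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE))
    return(list(p = wt$p.value,
                test = if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U",
                statistic = unname(wt$statistic), selection = selection))
  }
  # Bonferroni across the 2d per-coordinate checks so the screen keeps an
  # overall level near alpha_normality
  pn <- c(apply(A, 2L, shap_p), apply(B, 2L, shap_p))
  normal <- min(pn) >= alpha_normality / length(pn)
  n1 <- nrow(A); n2 <- nrow(B)
  if (normal && n1 + n2 > d + 2L) {
    S <- ((n1 - 1L) * cov(A) + (n2 - 1L) * cov(B)) / (n1 + n2 - 2L)
    diffm <- colMeans(A) - colMeans(B)
    T2 <- tryCatch((n1 * n2 / (n1 + n2)) * drop(crossprod(diffm, solve(S, diffm))),
                   error = function(e) NA_real_)
    if (is.finite(T2)) {
      Fst <- (n1 + n2 - d - 1L) / (d * (n1 + n2 - 2L)) * T2
      p <- pf(Fst, d, n1 + n2 - d - 1L, lower.tail = FALSE)
      return(list(p = p, test = "Hotelling T2", statistic = T2,
                  selection = sprintf("multivariate (d=%d); per-coordinate normality accepted", d)))
    }
  }
  # permutation test on centroid distance
  obs <- sqrt(sum((colMeans(A) - colMeans(B))^2))
  Z <- rbind(A, B)
  cnt <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(n1 + n2, n1)
      sqrt(sum((colMeans(Z[ix, , drop = FALSE]) -
                  colMeans(Z[-ix, , drop = FALSE]))^2)) >= obs
    }, TRUE))
  })
  list(p = (1 + cnt) / (1 + n_perm), test = "permutation centroid distance",
       statistic = obs,
       selection = sprintf("multivariate (d=%d); normality rejected or T2 unavailable", d))
}
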