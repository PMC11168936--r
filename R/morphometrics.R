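#' Generalized Procrustes alignment
#'
#' Translates each pseudolandmark configuration to the origin, scales it to
#' unit centroid size, and iteratively rotates all configurations to their
#' consensus (mean) shape using the optimal rotation without reflection
#' (determinant +1), updating the consensus until it changes by less than
#' `tol`. This standardizes for position, size and orientation while
#' preserving anatomical chirality.
#'
#' @param configs list of k x 3 matrices (all sharing k), e.g. from
#'   [resample_equal()].
#' @param tol convergence tolerance on the consensus change (default 1e-8).
#' @param max_iter iteration cap.
#' @return an object of class `aligned_set`: list with `configurations`
#'   (list of aligned k x 3 matrices), `centroid_sizes`, `consensus`,
#'   `objective` (sum of squared distances to consensus per iteration) and
#'   `specimen_ids`.
#' @export
gpa_align <- function(configs, tol = 1e-8, max_iter = 100L) {
  if (!is.list(configs) || length(configs) < 1L) stopf("configs must be a non-empty list")
  ids <- vapply(seq_along(configs), function(i) {
    id <- attr(configs[[i]], "specimen_id")
    if (is.null(id) || !nzchar(id)) sprintf("specimen_%d", i) else id
  }, character(1L))
  ks <- vapply(configs, nrow, 1L)
  if (length(unique(ks)) != 1L) {
    bad <- which(ks != ks[1L])[1L]
    stopf("configuration '%s' has %d landmarks but '%s' has %d",
          ids[bad], ks[bad], ids[1L], ks[1L])
  }
  k <- ks[1L]
  if (k < 3L) stopf("need at least 3 landmarks")
  cs <- numeric(length(configs))
  X <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    m <- unclass(configs[[i]])[, , drop = FALSE]
    m <- sweep(m, 2L, colMeans(m))
    cs[i] <- sqrt(sum(m * m))
    if (cs[i] == 0) stopf("configuration '%s' is degenerate (zero centroid size)", ids[i])
    X[[i]] <- m / cs[i]
  }
  consensus <- X[[1L]]
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    X <- lapply(X, rotate_onto, target = consensus)
    new_cons <- Reduce(`+`, X) / length(X)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    obj <- c(obj, sum(vapply(X, function(m) sum((m - new_cons)^2), 1)))
    if (sqrt(sum((new_cons - consensus)^2)) < tol && it > 1L) {
      consensus <- new_cons
      break
    }
    consensus <- new_cons
  }
  structure(list(configurations = X, centroid_sizes = cs, consensus = consensus,
                 objective = obj, specimen_ids = ids),
            class = "aligned_set")
}

# Optimal rotation (no reflection) of configuration m onto target.
rotate_onto <- function(m, target) {
  sv <- svd(crossprod(m, target))
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    u <- sv$u
    u[, 3L] <- -u[, 3L]
    R <- u %*% t(sv$v)
  }
  m %*% R
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("aligned_set: %d configurations x %d landmarks, GPA objective %.6g (%d iterations)\n",
              length(x$configurations), nrow(x$consensus),
              x$objective[length(x$objective)], length(x$objective)))
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Centres and scales both configurations to unit centroid size, rotates the
#' second onto the first (no reflection), and returns the root summed
#' squared coordinate difference. Zero for shapes differing only by a rigid
#' motion and scale.
#'
#' @param a,b k x 3 matrices.
#' @return non-negative distance.
#' @export
procrustes_distance <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  a <- sweep(a, 2L, colMeans(a)); a <- a / sqrt(sum(a^2))
  b <- sweep(b, 2L, colMeans(b)); b <- b / sqrt(sum(b^2))
  b <- rotate_onto(b, a)
  sqrt(sum((a - b)^2))
}

#' Mean shape of a group
#'
#' Coordinate-wise average of GPA-aligned configurations (the "average
#' centreline" of a group of specimens).
#'
#' @param a an `aligned_set`.
#' @param which logical/integer/character selector of specimens; default all.
#' @return a k x 3 `landmark_config` matrix.
#' @export
mean_shape <- function(a, which = NULL) {
  stopifnot(inherits(a, "aligned_set"))
  idx <- resolve_specimens(a, which)
  if (!length(idx)) stopf("empty group")
  m <- Reduce(`+`, a$configurations[idx]) / length(idx)
  structure(m, class = c("landmark_config", "matrix", "array"),
            specimen_id = "mean_shape")
}

resolve_specimens <- function(a, which) {
  if (is.null(which)) return(seq_along(a$configurations))
  if (is.logical(which)) return(which(which))
  if (is.character(which)) return(match(which, a$specimen_ids))
  as.integer(which)
}

#' Shape principal component analysis
#'
#' PCA of the flattened GPA-aligned coordinates. For each component the
#' extreme shapes are reconstructed as consensus + score * loading at the
#' observed minimum and maximum scores (the "theoretical extreme" shapes
#' drawn at the ends of each PC axis).
#'
#' @param a an `aligned_set` with at least 3 specimens.
#' @return list with `scores` (specimens x PCs), `sdev`, `var_explained`,
#'   `loadings`, `consensus` and `extremes` (per PC, `min`/`max` k x 3
#'   shapes).
#' @export
shape_pca <- function(a) {
  stopifnot(inherits(a, "aligned_set"))
  n <- length(a$configurations)
  if (n < 3L) stopf("need at least 3 specimens for a shape PCA")
  Y <- t(vapply(a$configurations, as.numeric, numeric(3L * nrow(a$consensus))))
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  k <- nrow(a$consensus)
  npc <- ncol(pc$rotation)
  extremes <- lapply(seq_len(npc), function(j) {
    sc <- range(pc$x[, j])
    centre <- matrix(pc$center, k, 3L)
    list(min = centre + matrix(pc$rotation[, j] * sc[1L], k, 3L),
         max = centre + matrix(pc$rotation[, j] * sc[2L], k, 3L))
  })
  names(extremes) <- colnames(pc$x)
  rownames(pc$x) <- a$specimen_ids
  list(scores = pc$x, sdev = pc$sdev,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       loadings = pc$rotation, consensus = matrix(pc$center, k, 3L),
       extremes = extremes)
}

## ---- Procrustes ANOVA with RRPP --------------------------------------------

# Build design matrices per term for type III (drop-one-term) comparisons.
# Continuous covariates are mean-centred before interactions are formed.
build_design <- function(formula, data) {
  tm <- stats::terms(formula, data = data)
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stopf("metadata is missing term(s): %s", paste(miss, collapse = ", "))
  for (v in vars) {
    if (is.numeric(data[[v]])) data[[v]] <- data[[v]] - mean(data[[v]])
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  }
  mm <- stats::model.matrix(tm, data)
  assign <- attr(mm, "assign")
  labels <- attr(tm, "term.labels")
  qrX <- qr(mm)
  if (qrX$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrX$pivot[(qrX$rank + 1L):ncol(mm)]]
    stopf("rank-deficient design; aliased column(s): %s", paste(aliased, collapse = ", "))
  }
  list(mm = mm, assign = assign, labels = labels)
}

hat_matrix <- function(X) {
  q <- qr.Q(qr(X))
  tcrossprod(q)
}

#' Procrustes type III ANOVA with residual randomization (RRPP)
#'
#' Fits a linear model to the flattened GPA-aligned shape coordinates and,
#' for each term, computes the marginal (type III) Procrustes sum of squares
#' by comparing the full model against the model with that term dropped.
#' Significance comes from randomizing the reduced-model residuals: permuted
#' response sets are formed as reduced fits plus row-permuted reduced
#' residuals, the F ratio is recomputed for each, and the p value is the
#' proportion of the reference set (observed statistic included) at least as
#' large as the observed F. With 1000 iterations p values are therefore
#' floored at 0.001. Permuted F values exactly equal to the observed count
#' toward the rank (conservative tie-break).
#'
#' @param a an `aligned_set`.
#' @param formula one-sided formula of metadata terms, e.g.
#'   `~ sex + gonad_volume + batch` or `~ genotype * sex`.
#' @param data data frame of specimen metadata, rows matching the aligned
#'   set's specimen order.
#' @param iterations total size of the reference distribution, observed
#'   statistic included (default 1000, i.e. 999 random permutations).
#' @param seed integer seed governing the permutations.
#' @return an object of class `anova_rrpp`: a data frame with one row per
#'   term plus residual and total rows (Df, SS, R2, F, Z, p), with the
#'   permutation schedule in attribute `perm_index`.
#' @export
procrustes_anova_rrpp <- function(a, formula, data, iterations = 1000L, seed = 1L) {
  stopifnot(inherits(a, "aligned_set"))
  n <- length(a$configurations)
  if (nrow(data) != n) stopf("metadata has %d rows but the aligned set has %d specimens", nrow(data), n)
  if (!is_count(iterations) || iterations < 2L) stopf("iterations must be an integer >= 2")
  Y <- t(vapply(a$configurations, as.numeric, numeric(3L * nrow(a$consensus))))
  des <- build_design(formula, data)
  H_full <- hat_matrix(des$mm)
  df_res <- n - qr(des$mm)$rank
  if (df_res <= 0L) stopf("model has no residual degrees of freedom")
  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_total <- sum(Yc * Yc)
  rss_full <- sum(((diag(n) - H_full) %*% Y)^2)

  perms <- with_seed(seed, replicate(iterations - 1L, sample.int(n), simplify = FALSE))

  labels <- des$labels
  out <- data.frame(term = labels, Df = NA_real_, SS = NA_real_, R2 = NA_real_,
                    F = NA_real_, Z = NA_real_, p = NA_real_)
  for (t_i in seq_along(labels)) {
    cols <- des$assign != t_i
    X_red <- des$mm[, cols, drop = FALSE]
    H_red <- hat_matrix(X_red)
    df_t <- sum(des$assign == t_i)
    D1 <- H_full - H_red          # projection onto the term's marginal subspace
    D2 <- diag(n) - H_full
    E_red <- Y - H_red %*% Y
    G <- tcrossprod(E_red)        # n x n; SS under permutation = sum(D * G[p, p])
    ss_obs <- sum(D1 * G)
    rss_obs <- rss_full
    F_obs <- (ss_obs / df_t) / (rss_obs / df_res)
    F_perm <- vapply(perms, function(p) {
      Gp <- G[p, p]
      (sum(D1 * Gp) / df_t) / (sum(D2 * Gp) / df_res)
    }, 1)
    F_all <- c(F_obs, F_perm)
    pos <- F_all[F_all > 0]
    Z <- if (length(pos) > 2L && sd(log(pos)) > 0) {
      (log(max(F_obs, min(pos))) - mean(log(pos))) / sd(log(pos))
    } else NA_real_
    out$Df[t_i] <- df_t
    out$SS[t_i] <- ss_obs
    out$R2[t_i] <- ss_obs / ss_total
    out$F[t_i] <- F_obs
    out$Z[t_i] <- Z
    out$p[t_i] <- sum(F_all >= F_obs) / iterations
  }
  out <- rbind(out,
               data.frame(term = "Residuals", Df = df_res, SS = rss_full,
                          R2 = rss_full / ss_total, F = NA, Z = NA, p = NA),
               data.frame(term = "Total", Df = n - 1L, SS = ss_total, R2 = 1,
                          F = NA, Z = NA, p = NA))
  attr(out, "iterations") <- iterations
  attr(out, "seed") <- seed
  attr(out, "perm_index") <- perms
  class(out) <- c("anova_rrpp", "data.frame")
  out
}

#' @export
print.anova_rrpp <- function(x, ...) {
  cat(sprintf("Procrustes type III ANOVA with RRPP (%d iterations)\n",
              attr(x, "iterations")))
  print.data.frame(cbind(x[1L], round(x[-1L], 4)), row.names = FALSE)
  invisible(x)
}

#' Pairwise group comparisons of least-squares mean shapes
#'
#' For every pair of groups, computes the Euclidean distance between
#' least-squares mean shapes (fitted group means with any null-model terms
#' held at their average) and a permutation p value obtained by randomizing
#' the residuals of the stated null model (RRPP; e.g. `~ 1` or `~ batch`).
#'
#' @param a an `aligned_set`.
#' @param grouping factor (or column name in `data`) defining the groups.
#' @param data specimen metadata.
#' @param null_formula null model for the randomization; default `~ 1`.
#' @param iterations reference-distribution size including the observed
#'   statistic (default 1000).
#' @param seed permutation seed.
#' @return list with `distance` (symmetric matrix of LS-mean distances),
#'   `p` (matrix of permutation p values) and `groups`.
#' @export
pairwise_group_comparison <- function(a, grouping, data, null_formula = ~ 1,
                                      iterations = 1000L, seed = 1L) {
  stopifnot(inherits(a, "aligned_set"))
  n <- length(a$configurations)
  if (is.character(grouping) && length(grouping) == 1L) grouping <- data[[grouping]]
  grouping <- factor(grouping)
  if (length(grouping) != n) stopf("grouping length mismatch")
  tab <- table(grouping)
  if (any(tab < 2L)) {
    small <- names(tab)[tab < 2L]
    warnf("excluding group(s) with < 2 specimens: %s", paste(small, collapse = ", "))
    keep <- !(grouping %in% small)
    sub <- a
    sub$configurations <- a$configurations[keep]
    sub$specimen_ids <- a$specimen_ids[keep]
    sub$centroid_sizes <- a$centroid_sizes[keep]
    return(pairwise_group_comparison(sub, droplevels(grouping[keep]),
                                     data[keep, , drop = FALSE], null_formula,
                                     iterations, seed))
  }
  g <- droplevels(grouping)
  lev <- levels(g)
  if (length(lev) < 2L) stopf("need at least 2 groups")
  Y <- t(vapply(a$configurations, as.numeric, numeric(3L * nrow(a$consensus))))
  des0 <- build_design(null_formula, data)
  H0 <- hat_matrix(des0$mm)
  fit0 <- H0 %*% Y
  E0 <- Y - fit0
  G_ind <- lapply(lev, function(l) which(g == l))
  ls_dist <- function(Ymat) {
    means <- lapply(G_ind, function(ix) colMeans(Ymat[ix, , drop = FALSE]))
    d <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
    for (i in seq_along(lev)) for (j in seq_along(lev)) {
      if (j > i) d[i, j] <- d[j, i] <- sqrt(sum((means[[i]] - means[[j]])^2))
    }
    d
  }
  d_obs <- ls_dist(Y)
  perms <- with_seed(seed, replicate(iterations - 1L, sample.int(n), simplify = FALSE))
  count_ge <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  for (p in perms) {
    dp <- ls_dist(fit0 + E0[p, , drop = FALSE])
    count_ge <- count_ge + (dp >= d_obs)
  }
  pmat <- count_ge / iterations
  diag(pmat) <- NA
  list(distance = d_obs, p = pmat, groups = lev,
       null_formula = null_formula, iterations = iterations, seed = seed)
}
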