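test_that("elastic registration is exact on identical inputs and recovers warps", {
  f <- rich_profile()
  w <- elastic_register(f, f)
  expect_lt(max(abs(w$gamma - w$grid)), 1 / (w$n_grid - 1))

  # f2(t) = f1(gamma_true(t)) with gamma_true(u) = u^1.6:
  # registering f2 onto f1 recovers the inverse warp u^(1/1.6)
  u <- seq(0, 1, length.out = 201)
  f2 <- scalar_profile(u, approx(u, f$values, u^1.6)$y, "normalized_curvature")
  w2 <- elastic_register(f, f2, n_grid = 201L)
  expect_lt(max(abs(w2$gamma - w2$grid^(1 / 1.6))), 0.03)

  # constants: every warping ties; the identity is returned
  cf <- scalar_profile(u, rep(2, 201), "intensity")
  cg <- scalar_profile(u, rep(5, 201), "intensity")
  wc <- elastic_register(cf, cg)
  expect_equal(wc$gamma, wc$grid, tolerance = 1e-12)

  short <- scalar_profile(1:5, 1:5, "intensity")
  expect_error(elastic_register(short, f), "at least 10")
})

test_that("curvature distance matches closed forms and the discretized-sum oracle", {
  u <- seq(0, 1, length.out = 120)
  k1 <- scalar_profile(u, rep(2, 120), "normalized_curvature")
  k2 <- scalar_profile(u, rep(5, 120), "normalized_curvature")
  expect_equal(curvature_distance(k1, k1), 0)
  expect_equal(curvature_distance(k1, k2), 3, tolerance = 1e-9)

  # direct evaluation of the 200-point discretized sum, given the warping
  f1 <- rich_profile(181L, "a")
  f2 <- scalar_profile(seq(0, 1, length.out = 181),
                       cos(3 * pi * seq(0, 1, length.out = 181)) + 1.2,
                       "normalized_curvature", specimen_id = "b")
  n_grid <- 200L
  direct_one_way <- function(fa, fb) {
    va <- approx(seq(0, 1, length.out = length(fa$values)), fa$values,
                 seq(0, 1, length.out = n_grid))$y
    vb <- approx(seq(0, 1, length.out = length(fb$values)), fb$values,
                 seq(0, 1, length.out = n_grid))$y
    w <- elastic_register(fa, fb, n_grid = n_grid)
    sn <- seq(0, 1, length.out = n_grid)
    terms <- (approx(sn, va, sn)$y -
                approx(sn, vb, approx(w$grid, w$gamma, sn)$y, rule = 2)$y)^2
    d_reg <- sqrt(sum(terms) / n_grid)
    min(d_reg, sqrt(mean((va - vb)^2)))
  }
  oracle <- (direct_one_way(f1, f2) + direct_one_way(f2, f1)) / 2
  expect_equal(curvature_distance(f1, f2, n_grid = n_grid), oracle,
               tolerance = 1e-10)

  # registration never increases the distance over the unregistered RMS
  v1 <- approx(seq_along(f1$values), f1$values, seq(1, 181, length.out = 200))$y
  v2 <- approx(seq_along(f2$values), f2$values, seq(1, 181, length.out = 200))$y
  expect_lte(curvature_distance(f1, f2), sqrt(mean((v1 - v2)^2)) + 1e-12)

  # symmetric by construction
  expect_equal(curvature_distance(f1, f2), curvature_distance(f2, f1))
})

test_that("distance matrices are recomputable element-wise and normalizable", {
  u <- seq(0, 1, length.out = 101)
  mk <- function(i) scalar_profile(u, sin(2 * pi * u + i / 2) + i / 4,
                                   "normalized_curvature",
                                   specimen_id = paste0("s", i))
  profs <- lapply(1:4, mk)
  d <- distance_matrix(profs, n_grid = 101L)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d[i, j], curvature_distance(profs[[i]], profs[[j]], 101L))
  }
  expect_equal(unname(diag(unclass(d))), rep(0, 4))

  dup <- distance_matrix(list(profs[[1]], profs[[1]], profs[[1]]), n_grid = 101L)
  expect_equal(max(dup), 0)

  rel <- distance_matrix(profs, relative = TRUE, n_grid = 101L)
  expect_equal(max(rel), 1)
})

test_that("MDS reproduces Euclidean-embeddable distances with near-zero stress", {
  set.seed(2)
  P <- matrix(rnorm(45), 15, 3)
  D <- as.matrix(dist(P))
  dimnames(D) <- list(paste0("s", 1:15), paste0("s", 1:15))
  emb <- mds_embed(D, dim = 3L, seed = 1L)
  De <- as.matrix(dist(emb$points))
  expect_lt(max(abs(De - D)) / max(D), 1e-6)
  expect_lt(emb$stress, 1e-6)
  expect_true(all(diff(emb$stress_path) <= 1e-12))  # SMACOF monotone

  # regular simplex: all embedded distances equal
  S <- matrix(1, 4, 4) - diag(4)
  es <- mds_embed(S, dim = 3L, seed = 1L)
  ds <- as.matrix(dist(es$points))
  off <- ds[upper.tri(ds)]
  expect_lt(diff(range(off)) / mean(off), 0.01)

  bad <- D; bad[1, 2] <- bad[1, 2] + 1
  expect_error(mds_embed(bad), "symmetric")
})

test_that("confidence ellipsoids have nominal coverage", {
  set.seed(7)
  S <- matrix(c(2, .5, .1, .5, 1, .2, .1, .2, .7), 3, 3)
  X <- matrix(rnorm(4000 * 3), 4000, 3) %*% chol(S)
  ell <- group_ellipsoid(X, 0.95)
  expect_lt(abs(mean(ellipsoid_contains(ell, X)) - 0.95), 0.02)

  iso <- matrix(rnorm(5000 * 3), 5000, 3)
  e_iso <- group_ellipsoid(iso)
  expect_lt(diff(range(e_iso$radii)) / mean(e_iso$radii), 0.1)

  expect_error(group_ellipsoid(matrix(rnorm(9), 3, 3)), "at least 4")
  degenerate <- cbind(rnorm(10), rnorm(10), 0)
  expect_error(group_ellipsoid(degenerate), "singular")
})

test_that("the location test selects an applicable test and behaves at the extremes", {
  set.seed(5)
  A <- matrix(rnorm(60), 20, 3)
  same <- location_test(A, A)
  expect_equal(same$p, 1, tolerance = 1e-9)

  B <- A + 5  # large offset
  sep <- location_test(A, B)
  expect_lt(sep$p, 0.001)
  expect_match(sep$test, "Hotelling")

  # univariate branches
  a <- rnorm(15); b <- rnorm(15)
  t_res <- location_test(a, b)
  expect_match(t_res$test, "t-test")
  a_heavy <- rt(30, df = 1); b_heavy <- rt(30, df = 1)
  r_res <- location_test(a_heavy, b_heavy)
  expect_match(r_res$test, "Mann-Whitney")

  expect_error(location_test(A, matrix(rnorm(10), 5, 2)), "dimensionality")
})
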