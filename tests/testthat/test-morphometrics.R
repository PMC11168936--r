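test_that("GPA alignment removes translation, scale and rotation", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  R <- random_rotation(3)
  Y <- 2.5 * X %*% R + matrix(rep(c(5, -3, 8), each = 20), 20, 3)
  expect_lt(procrustes_distance(X, Y), 1e-10)

  al <- gpa_align(list(X, Y))
  expect_lt(sqrt(sum((al$configurations[[1]] - al$configurations[[2]])^2)), 1e-10)
  # consensus centred at origin, configurations at unit centroid size
  expect_equal(colMeans(al$consensus), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sum(al$configurations[[1]]^2), 1, tolerance = 1e-12)

  # single configuration: consensus is the centred, scaled input
  one <- gpa_align(list(X))
  Xc <- sweep(X, 2, colMeans(X)); Xc <- Xc / sqrt(sum(Xc^2))
  expect_equal(one$consensus, Xc, tolerance = 1e-12)

  expect_error(gpa_align(list(X, X[1:10, ])), "landmarks")
})

test_that("GPA objective is non-increasing and matches an independent superposition oracle", {
  set.seed(7)
  configs <- lapply(1:8, function(i) matrix(rnorm(30), 10, 3))
  al <- gpa_align(configs)
  expect_true(all(diff(al$objective) <= 1e-12))

  skip_if_not_installed("vegan")
  # two-shape oracle: vegan's Procrustes superposition residual
  A <- matrix(rnorm(30), 10, 3)
  B <- A + 0.1 * matrix(rnorm(30), 10, 3)
  Ac <- sweep(A, 2, colMeans(A)); Ac <- Ac / sqrt(sum(Ac^2))
  Bc <- sweep(B, 2, colMeans(B)); Bc <- Bc / sqrt(sum(Bc^2))
  veg <- vegan::procrustes(Ac, Bc, scale = FALSE, symmetric = FALSE)
  d_veg <- sqrt(sum((veg$Yrot - Ac)^2))
  expect_equal(procrustes_distance(A, B), d_veg, tolerance = 1e-6)
})

test_that("group mean shapes average aligned coordinates", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  al <- gpa_align(list(X, X, X))
  expect_equal(unclass(mean_shape(al)), al$configurations[[1]], tolerance = 1e-9,
               ignore_attr = TRUE)

  al2 <- gpa_align(list(X, X + 0.05 * matrix(rnorm(30), 10, 3)))
  mid <- (al2$configurations[[1]] + al2$configurations[[2]]) / 2
  expect_equal(unclass(mean_shape(al2)), mid, ignore_attr = TRUE)
  expect_error(mean_shape(al, integer(0)), "empty")
})

test_that("shape PCA conserves variance and recovers a generator axis", {
  coh <- fast_cohort(n_per_group = 5L, seed = 21L)
  al <- aligned_from_cohort(coh, k = 150L)
  pca <- shape_pca(al)
  Y <- t(vapply(al$configurations, as.numeric, numeric(450)))
  expect_equal(sum(pca$sdev^2), sum(apply(Y, 2, var)), tolerance = 1e-9)

  # the dominant shape axis separates the dimorphic groups
  meta <- cohort_metadata(coh)
  r <- cor(pca$scores[, 1], as.numeric(meta$sex == "female"))
  expect_gt(abs(r), 0.9)

  # reconstruction at score 0 is the consensus
  recon0 <- pca$consensus
  expect_equal(recon0, matrix(colMeans(Y), 150, 3), tolerance = 1e-9)
})

test_that("RRPP ANOVA reports the printed p floor and rejects bad designs", {
  coh <- fast_cohort(n_per_group = 8L, seed = 3L)
  meta <- cohort_metadata(coh)
  al <- aligned_from_cohort(coh, k = 200L)
  an <- procrustes_anova_rrpp(al, ~ sex, meta, iterations = 1000L, seed = 5L)
  expect_equal(an$p[an$term == "sex"], 0.001)  # floor at 1/iterations
  expect_gt(an$R2[an$term == "sex"], 0.3)

  # determinism
  an2 <- procrustes_anova_rrpp(al, ~ sex, meta, iterations = 1000L, seed = 5L)
  expect_identical(an$p, an2$p)

  meta$flat <- 1
  expect_error(procrustes_anova_rrpp(al, ~ sex + flat, meta), "aliased")
  expect_error(procrustes_anova_rrpp(al, ~ sex + missing_term, meta), "missing")
})

test_that("ANOVA table is internally consistent on a balanced design", {
  coh <- fast_cohort(n_per_group = 6L, seed = 9L)
  meta <- cohort_metadata(coh)
  al <- aligned_from_cohort(coh, k = 120L)
  an <- procrustes_anova_rrpp(al, ~ sex + batch, meta, iterations = 200L, seed = 2L)
  ss <- an$SS
  # balanced, orthogonal factors: term SS + residual SS = total SS
  expect_equal(sum(ss[an$term %in% c("sex", "batch", "Residuals")]),
               ss[an$term == "Total"], tolerance = 1e-6)
  expect_true(all(ss >= 0))
  expect_true(all(an$p[1:2] >= 1 / 200 & an$p[1:2] <= 1, na.rm = TRUE))
})

test_that("RRPP p values are calibrated and uniform under the null", {
  set.seed(42)
  n <- 14L; k <- 10L
  base <- matrix(rnorm(k * 3), k, 3)
  runs <- 300L
  pvals <- vapply(seq_len(runs), function(r) {
    cfgs <- lapply(seq_len(n), function(i) base + matrix(rnorm(k * 3, sd = 0.3), k, 3))
    al <- gpa_align(cfgs)
    md <- data.frame(noise = rnorm(n))
    procrustes_anova_rrpp(al, ~ noise, md, iterations = 200L, seed = r)$p[1]
  }, 1)
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 0.035)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pairwise LS-mean comparisons separate true groups and not shuffled copies", {
  coh <- fast_cohort(n_per_group = 8L, seed = 3L)
  meta <- cohort_metadata(coh)
  al <- aligned_from_cohort(coh, k = 200L)
  pw <- pairwise_group_comparison(al, meta$sex, meta, ~ 1,
                                  iterations = 1000L, seed = 6L)
  expect_equal(pw$p["female", "male"], 0.001)
  expect_equal(pw$distance, t(pw$distance))
  expect_equal(diag(pw$distance), c(female = 0, male = 0))

  # shuffled labels on one homogeneous group: p rarely small
  set.seed(10)
  base <- matrix(rnorm(36), 12, 3)
  cfgs <- lapply(1:16, function(i) base + matrix(rnorm(36, sd = 0.2), 12, 3))
  aln <- gpa_align(cfgs)
  md <- data.frame(g = rep(c("a", "b"), 8))
  hits <- vapply(1:40, function(r) {
    md$g <- sample(md$g)
    pairwise_group_comparison(aln, md$g, md, ~ 1, iterations = 100L,
                              seed = r)$p["a", "b"] <= 0.05
  }, TRUE)
  expect_lte(mean(hits), 0.2)
})
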