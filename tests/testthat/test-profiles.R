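test_that("anchor alignment maps R3 to 50% and bins correctly", {
  u <- seq(0, 1, length.out = 200)
  # marker: a narrow spike at each trace's anchor
  mk <- function(anchor, id) {
    v <- exp(-(u - anchor)^2 / (2 * 0.01^2))
    scalar_profile(u, v, "intensity", specimen_id = id, anchor = anchor)
  }
  b <- align_and_bin(list(mk(0.4, "a"), mk(0.6, "b")), n_bins = 40L)
  expect_equal(nrow(b), 40L)
  expect_equal(attr(b, "anchor"), 0.5)
  # both spikes land in the central bins after anchoring (the anchor sits on
  # the 20/21 bin boundary)
  per <- attr(b, "per_specimen")
  expect_true(which.max(per[1, ]) %in% 20:21)
  expect_true(which.max(per[2, ]) %in% 20:21)

  cst <- lapply(1:3, function(i) scalar_profile(u, rep(2.5, 200), "intensity",
                                                specimen_id = paste0("c", i),
                                                anchor = 0.5))
  bc <- align_and_bin(cst)
  expect_equal(bc$mean, rep(2.5, 40))
  expect_equal(bc$sd, rep(0, 40))
  expect_equal(bc$n, rep(3L, 40))

  bad <- scalar_profile(u, u, "intensity", anchor = 1)
  expect_error(align_and_bin(list(bad)), "degenerate")
})

test_that("unit normalization maps range to [0, 1] and is affine invariant", {
  f <- scalar_profile(1:3, c(2, 4, 6), "intensity")
  expect_equal(unit_normalize(f)$values, c(0, 0.5, 1))

  set.seed(3)
  g <- scalar_profile(1:50, rnorm(50), "intensity")
  gn <- unit_normalize(g)
  expect_equal(range(gn$values), c(0, 1))
  g2 <- g; g2$values <- 3.7 * g$values - 11
  expect_equal(unit_normalize(g2)$values, gn$values, tolerance = 1e-12)

  flat <- scalar_profile(1:10, rep(1, 10), "intensity")
  expect_error(unit_normalize(flat), "constant")
})

test_that("all-pairs correlation yields n_curvature x n_intensity coefficients", {
  u <- seq(0, 1, length.out = 60)
  mk <- function(i, kind) scalar_profile(u, sin(2 * pi * u + i / 3) + i / 10,
                                         kind, specimen_id = paste0(kind, i))
  curv <- lapply(1:5, mk, kind = "normalized_curvature")
  inten <- lapply(1:3, mk, kind = "intensity")
  cs <- pairwise_profile_correlation(curv, inten, n_grid = 41L)
  expect_equal(dim(cs$coefficients), c(5L, 3L))
  expect_equal(nrow(cs$provenance), 15L)
  expect_true(all(abs(cs$coefficients) <= 1 + 1e-12))

  # self-pairing: diagonal r = 1
  self <- pairwise_profile_correlation(curv, curv, n_grid = 41L)
  expect_equal(unname(diag(self$coefficients)), rep(1, 5), tolerance = 1e-9)

  expect_error(pairwise_profile_correlation(list(), inten), "empty")
})

test_that("AR fitting recovers known coefficients and simulates a null", {
  prm <- generator_params(intensity_peak_amp = 0, ar_coeffs = 0.6,
                          ar_noise_sd = 0.1)
  tr <- generate_intensity_trace(3000L, prm, seed = 2L)
  fit <- gutmorph:::fit_ar(tr$values, 1L)
  se <- sqrt((1 - 0.6^2) / 3000)  # asymptotic sd of the AR(1) estimate
  expect_lt(abs(fit$phi - 0.6), 2 * se)

  u <- seq(0, 1, length.out = 120)
  curv <- lapply(1:2, function(i) {
    scalar_profile(u, sin(2 * pi * u + i), "normalized_curvature",
                   specimen_id = paste0("c", i))
  })
  inten <- lapply(1:3, function(i) {
    generate_intensity_trace(120L, generator_params(), seed = i,
                             specimen_id = paste0("i", i))
  })
  nl <- ar_null(inten, curv, n_sim = 4L, order = 1L, seed = 9L, n_grid = 41L)
  expect_length(nl$simulated, 12L)
  expect_equal(dim(nl$null_correlations$coefficients), c(2L, 12L))

  # seed-determinism and boundary case
  nl2 <- ar_null(inten, curv, n_sim = 4L, order = 1L, seed = 9L, n_grid = 41L)
  expect_equal(nl$null_correlations$coefficients, nl2$null_correlations$coefficients)
  empty <- ar_null(inten, curv, n_sim = 0L, seed = 1L)
  expect_length(empty$simulated, 0L)
  expect_null(empty$null_correlations)
  expect_error(ar_null(list(scalar_profile(1:5, rnorm(5), "intensity")),
                       order = 10L), "order")
})

test_that("null correlation distributions are seed-invariant and power-shifted", {
  u <- seq(0, 1, length.out = 100)
  bump <- exp(-(u - 0.5)^2 / (2 * 0.05^2))
  curv <- lapply(1:3, function(i) {
    scalar_profile(u, bump + 0.05 * sin(9 * u + i), "normalized_curvature",
                   specimen_id = paste0("c", i))
  })
  prm <- generator_params(intensity_peak_pos = 0.5, intensity_peak_amp = 1,
                          ar_noise_sd = 0.15)
  inten <- lapply(1:6, function(i) {
    unit_normalize(generate_intensity_trace(100L, prm, seed = 10 + i,
                                            specimen_id = paste0("i", i)))
  })
  obs <- pairwise_profile_correlation(curv, inten, n_grid = 41L)
  n1 <- ar_null(inten, curv, n_sim = 8L, seed = 1L, n_grid = 41L)
  n2 <- ar_null(inten, curv, n_sim = 8L, seed = 2L, n_grid = 41L)
  # same null distribution under different seeds
  ks <- suppressWarnings(stats::ks.test(as.numeric(n1$null_correlations$coefficients),
                                        as.numeric(n2$null_correlations$coefficients)))
  expect_gt(ks$p.value, 0.01)
  # a true shared peak right-shifts the observed correlations
  expect_gt(median(obs$coefficients),
            median(n1$null_correlations$coefficients))
})

test_that("binned-vector correlation matches the closed formula", {
  b1 <- structure(data.frame(bin = 1:5, mid = (1:5 - 0.5) / 5,
                             mean = c(1, 3, 2, 5, 4), sd = 0, n = 3),
                  class = c("binned_profile", "data.frame"))
  b2 <- b1; b2$mean <- c(2, 1, 4, 3, 5)
  expect_equal(curvature_intensity_correlation(b1, b2),
               cor(c(1, 3, 2, 5, 4), c(2, 1, 4, 3, 5)))
  expect_equal(curvature_intensity_correlation(b1, b1), 1)

  ramp <- b1; ramp$mean <- 1:5
  anti <- b1; anti$mean <- 5:1
  expect_equal(curvature_intensity_correlation(ramp, anti), -1)

  flat <- b1; flat$mean <- rep(2, 5)
  expect_error(curvature_intensity_correlation(b1, flat), "zero-variance")
})
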