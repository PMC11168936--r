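test_that("local cubic fits reproduce polynomial curves to machine precision", {
  s <- seq(0, 10, length.out = 60)
  cubic <- cbind(1 + 2 * s - 0.3 * s^2 + 0.05 * s^3,
                 -2 + 0.5 * s + 0.1 * s^2 - 0.02 * s^3,
                 3 * s)
  # parameterize by the true abscissa, not chord length: feed a param_curve
  p <- structure(list(points = cubic, s = s, L = 10, specimen_id = "poly",
                      landmarks = NULL), class = "param_curve")
  fit <- local_cubic_fit(p, s_star = 4, delta = 3)
  expect_equal(fit$d1, c(2 - 0.6 * 4 + 0.15 * 16, 0.5 + 0.2 * 4 - 0.06 * 16, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$d2, c(-0.6 + 0.3 * 4, 0.2 - 0.12 * 4, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$d3, c(0.3, -0.12, 0), tolerance = 1e-9, ignore_attr = TRUE)

  line <- parameterize(centreline(cbind(seq(0, 9), 0, 0)))
  lf <- local_cubic_fit(line, 4.5, 3)
  expect_equal(lf$d2, c(0, 0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(lf$d3, c(0, 0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(local_cubic_fit(line, 4.5, 0.4), "resample")
})

test_that("curvature and torsion match the closed forms for circle and helix", {
  kt <- curvature_torsion(circle_curve(r = 4, n = 1000L), n_eval = 1000L)
  expect_equal(median(kt$curvature$values), 1 / 4, tolerance = 0.01)
  expect_lt(max(abs(kt$torsion$values), na.rm = TRUE), 0.01)

  # helix a, c: kappa = a/(a^2+c^2), tau = c/(a^2+c^2)
  kt <- curvature_torsion(helix_curve(a = 2, c = 1, n = 900L), n_eval = 900L)
  expect_equal(median(kt$curvature$values), 2 / 5, tolerance = 0.01)
  expect_equal(median(kt$torsion$values, na.rm = TRUE), 1 / 5, tolerance = 0.01)
})

test_that("torsion flips sign under reflection, curvature does not", {
  pts <- helix_points(n = 700L)
  mirrored <- pts
  mirrored[, 3] <- -mirrored[, 3]
  kt <- curvature_torsion(parameterize(centreline(pts)), n_eval = 700L)
  km <- curvature_torsion(parameterize(centreline(mirrored)), n_eval = 700L)
  expect_equal(km$curvature$values, kt$curvature$values, tolerance = 1e-8)
  expect_equal(km$torsion$values, -kt$torsion$values, tolerance = 1e-8)
})

test_that("normalized curvature is scale invariant and 2*pi on circles", {
  for (r in c(0.5, 7, 700)) {
    p <- circle_curve(r = r, n = 1200L)
    nk <- normalize_by_length(curvature_torsion(p, n_eval = 1200L)$curvature)
    expect_equal(median(nk$values), 2 * pi, tolerance = 0.01)
  }
  # helix family with fixed a/c ratio: identical normalized profiles
  nk1 <- normalize_by_length(
    curvature_torsion(helix_curve(a = 1, c = 0.5, n = 600L), n_eval = 600L)$curvature)
  nk3 <- normalize_by_length(
    curvature_torsion(helix_curve(a = 3, c = 1.5, n = 600L), n_eval = 600L)$curvature)
  expect_equal(nk1$values, nk3$values, tolerance = 1e-6)

  k <- curvature_torsion(circle_curve(), n_eval = 200L)$curvature
  expect_error(normalize_by_length(k, L = -1), "positive")
  f <- scalar_profile(1:10, 1:10, "intensity")
  expect_error(normalize_by_length(f), "curvature or torsion")
})

test_that("the zero-phase low-pass filter has the expected frequency response", {
  s <- seq_len(300) - 1
  const <- scalar_profile(s, rep(4.2, 300), "intensity")
  expect_equal(smooth_profile(const)$values, rep(4.2, 300), tolerance = 1e-10)

  hi <- scalar_profile(s, sin(pi * 0.8 * s), "intensity")   # 0.8 x Nyquist
  expect_lt(max(abs(smooth_profile(hi)$values[50:250])), 0.1)  # >= 90% attenuated

  lo <- scalar_profile(s, sin(pi * 0.05 * s), "intensity")  # well below cutoff
  expect_gt(max(abs(smooth_profile(lo)$values[50:250])), 0.95)  # within 5%

  short <- scalar_profile(1:8, rnorm(8), "intensity")
  expect_warning(smooth_profile(short), "too few samples")
})

test_that("radius profiles recover generated tube radii", {
  straight <- parameterize(centreline(cbind(seq(0, 500, length.out = 100), 0, 0)))
  tube <- generate_tube_mesh(straight, 10, n_ring = 16L)
  rp <- radius_profile(straight, tube)
  expect_equal(median(rp$values), 10, tolerance = 0.01)

  # cone-shaped tube: monotone taper follows the generator
  taper <- seq(20, 5, length.out = 100)
  cone <- generate_tube_mesh(straight, taper, n_ring = 16L)
  rc <- radius_profile(straight, cone)
  expect_equal(rc$values[10:90], taper[10:90], tolerance = 0.1)
  expect_lt(mean(diff(rc$values[10:90])), 0)

  expect_error(surface_mesh(matrix(0, 0, 3), matrix(integer(0), 0, 3)),
               "at least 4 vertices")
  outside <- parameterize(centreline(cbind(seq(-100, 600, length.out = 50), 0, 0)))
  expect_warning(radius_profile(outside, tube), "bounding box")
})

test_that("tilt is the angle between leading eigendirections, in [0, 90]", {
  whole <- parameterize(centreline(cbind(seq(0, 100, length.out = 50),
                                         rnorm(50, sd = 0.5), rnorm(50, sd = 0.5))))
  sub_aligned <- parameterize(centreline(cbind(seq(40, 60, length.out = 20),
                                               rnorm(20, sd = 0.01),
                                               rnorm(20, sd = 0.01))))
  expect_lt(tilt_angle(whole, sub_aligned), 2)

  sub_perp <- parameterize(centreline(cbind(50 + rnorm(20, sd = 0.01),
                                            seq(-10, 10, length.out = 20),
                                            rnorm(20, sd = 0.01))))
  expect_gt(tilt_angle(whole, sub_perp), 88)

  # joint rotation leaves the angle unchanged
  R <- random_rotation(9)
  rot <- function(p) parameterize(centreline(p$points %*% R))
  expect_equal(tilt_angle(rot(whole), rot(sub_perp)),
               tilt_angle(whole, sub_perp), tolerance = 1e-6)

  th <- seq(0, 2 * pi, length.out = 201)[-201]  # exactly symmetric ring
  iso <- parameterize(centreline(cbind(cos(th), sin(th), 0)))
  expect_error(tilt_angle(whole, iso), "degenerate")
})
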