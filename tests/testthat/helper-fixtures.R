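# Analytic fixtures shared across test files. Everything is built in code;
# closed-form quantities (helix curvature/torsion, circle circumference,
# sphere separations) serve as independent oracles.

helix_points <- function(a = 1, c = 1, n = 800L, turns = 1) {
  tt <- seq(0, 2 * pi * turns, length.out = n)
  cbind(a * cos(tt), a * sin(tt), c * tt)
}

circle_points <- function(r = 1, n = 1000L) {
  th <- seq(0, 2 * pi, length.out = n)
  cbind(r * cos(th), r * sin(th), 0)
}

helix_curve <- function(...) parameterize(centreline(helix_points(...)))

circle_curve <- function(...) parameterize(centreline(circle_points(...)))

random_rotation <- function(seed = 1) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# A wiggly profile with structure everywhere (identifiable warps).
rich_profile <- function(n = 201L, id = "rich") {
  u <- seq(0, 1, length.out = n)
  scalar_profile(u, sin(4 * pi * u) + 2 * u, "normalized_curvature",
                 specimen_id = id)
}

# Regular icosahedron (12 vertices, 20 faces), circumradius 1.
icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(1 + p^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  surface_mesh(v, f, organ_name = "icosahedron")
}

# Brute-force nearest-neighbour oracle: plain double loop.
brute_force_nn <- function(from, to) {
  vapply(seq_len(nrow(from)), function(i) {
    sqrt(min(colSums((t(to) - from[i, ])^2)))
  }, 1)
}

# Small cohort settings that keep unit tests fast.
fast_cohort <- function(n_per_group = 4L, seed = 11L, n_points = 400L) {
  generate_cohort(cohort_spec(n_per_group = n_per_group, seed = seed),
                  n_points = n_points)
}

aligned_from_cohort <- function(cohort, k = 200L) {
  gpa_align(lapply(cohort, function(sp) {
    resample_equal(parameterize(sp$centreline), k)
  }))
}
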