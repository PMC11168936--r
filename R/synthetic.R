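# Seed-deterministic synthetic cohorts: centrelines with a known anterior
# run / tilted loop stack / terminal coil architecture, tube and neighbour
# meshes, and intensity traces with an autoregressive noise component. The
# loop region is a helix, so its curvature amplitude is known in closed form
# and every generated geometric property can be recovered by the downstream
# estimators.

#' Generator parameters for one group
#'
#' Defaults describe a plausible adult fly gut at micrometre scale; the two
#' sexes differ in total length, loop curvature amplitude, loop tilt and
#' tube radius (see [female_params()] / [male_params()]).
#'
#' @param total_length total centreline length in micrometres.
#' @param loop_count number of turns in the midgut loop stack.
#' @param loop_curvature_amp curvature amplitude on the loop region (1/um).
#' @param loop_tilt_deg tilt of the loop-stack axis to the main body axis.
#' @param hindgut_coil_turns turns of the terminal coil (0 = straight).
#' @param tube_radius_mean mean tube radius in micrometres.
#' @param noise_sd amplitude (um) of the smooth random displacement field.
#' @param intensity_peak_pos position of the intensity elevation as a
#'   fraction of gut length (the R3 anchor).
#' @param intensity_peak_amp height of the elevation over baseline.
#' @param ar_coeffs AR coefficients of the intensity noise (must be
#'   stationary).
#' @param ar_noise_sd innovation standard deviation of that AR process.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(total_length = 6000, loop_count = 4,
                             loop_curvature_amp = 0.005, loop_tilt_deg = 20,
                             hindgut_coil_turns = 1.5, tube_radius_mean = 80,
                             noise_sd = 30, intensity_peak_pos = 0.5,
                             intensity_peak_amp = 1, ar_coeffs = 0.6,
                             ar_noise_sd = 0.1) {
  p <- list(total_length = total_length, loop_count = loop_count,
            loop_curvature_amp = loop_curvature_amp,
            loop_tilt_deg = loop_tilt_deg,
            hindgut_coil_turns = hindgut_coil_turns,
            tube_radius_mean = tube_radius_mean, noise_sd = noise_sd,
            intensity_peak_pos = intensity_peak_pos,
            intensity_peak_amp = intensity_peak_amp,
            ar_coeffs = as.numeric(ar_coeffs), ar_noise_sd = ar_noise_sd)
  validate_params(p)
  structure(p, class = "generator_params")
}

validate_params <- function(p) {
  if (!is.numeric(p$total_length) || p$total_length <= 0) {
    stopf("total_length must be positive (got %.3g)", p$total_length)
  }
  if (!is_count(p$loop_count) || p$loop_count < 1L) stopf("loop_count must be an integer >= 1")
  if (p$loop_curvature_amp <= 0) stopf("loop_curvature_amp must be positive")
  if (p$intensity_peak_pos < 0 || p$intensity_peak_pos > 1) {
    stopf("intensity_peak_pos must be in [0, 1]")
  }
  if (p$tube_radius_mean <= 0) stopf("tube_radius_mean must be positive")
  if (p$noise_sd < 0 || p$ar_noise_sd < 0) stopf("noise standard deviations must be >= 0")
  if (!ar_stationary(p$ar_coeffs)) {
    stopf("ar_coeffs define a non-stationary process (root inside the unit circle)")
  }
  invisible(p)
}

#' @rdname generator_params
#' @export
female_params <- function() {
  generator_params(total_length = 6500, loop_curvature_amp = 0.006,
                   loop_tilt_deg = 15, tube_radius_mean = 90)
}

#' @rdname generator_params
#' @export
male_params <- function() {
  generator_params(total_length = 5500, loop_count = 2,
                   loop_curvature_amp = 0.004, loop_tilt_deg = 30,
                   tube_radius_mean = 70)
}

#' Cohort specification
#'
#' @param n_per_group specimens per sex (>= 1).
#' @param female,male per-sex [generator_params()].
#' @param batch_labels character vector of batch names, cycled over
#'   specimens; an empty vector falls back to a single batch (with a
#'   message).
#' @param seed integer seed; fully determines the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10L, female = female_params(),
                        male = male_params(),
                        batch_labels = c("batch1", "batch2"), seed = 1L) {
  if (!is_count(n_per_group) || n_per_group < 1L) stopf("n_per_group must be an integer >= 1")
  if (!length(batch_labels)) {
    message("empty batch list; assuming a single batch")
    batch_labels <- "batch1"
  }
  structure(list(n_per_group = as.integer(n_per_group), female = female,
                 male = male, batch_labels = as.character(batch_labels),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Regional length fractions of the synthetic gut.
REGION_FRACTIONS <- c(anterior = 0.25, loops = 0.55, hindgut = 0.20)

#' Generate one synthetic centreline
#'
#' The curve is an open polyline of three joined segments: an anterior run
#' (a gentle planar meander along the body axis), a midgut loop stack
#' modelled as a helix with curvature exactly `loop_curvature_amp` whose
#' axis is tilted `loop_tilt_deg` from the body axis, and a terminal
#' hindgut coil. Landmarks `loop_start`, `loop_end` and `R3` (the arclength
#' midpoint of the loop region) are recorded on the curve. A smooth random
#' displacement field of amplitude `noise_sd` is added last; with
#' `noise_sd = 0` the loop-region curvature equals the requested amplitude
#' analytically.
#'
#' @param params a [generator_params()].
#' @param seed integer seed; identical seed and parameters reproduce the
#'   curve exactly.
#' @param n_points number of polyline points (default 1000).
#' @param specimen_id,sex,batch metadata.
#' @return a [centreline()].
#' @export
generate_centreline <- function(params, seed = 1L, n_points = 1000L,
                                specimen_id = "synthetic", sex = NA_character_,
                                batch = NA_character_) {
  validate_params(params)
  if (!is_count(n_points) || n_points < 12L) stopf("n_points must be an integer >= 12")
  L <- params$total_length
  len <- REGION_FRACTIONS * L
  n_seg <- pmax(4L, round(REGION_FRACTIONS * n_points))

  # anterior: unit-speed planar meander, heading angle a sine of arclength
  n_a <- n_seg[[1L]]
  ds <- len[[1L]] / (n_a - 1L)
  th <- 0.15 * sin(2 * pi * seq(0, 1, length.out = n_a - 1L))
  steps <- cbind(cos(th), sin(th), 0) * ds
  ant <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))

  # loop stack: helix with curvature kappa = rho / R^2, R = arclength radius
  kappa <- params$loop_curvature_amp
  n_turns <- params$loop_count
  R <- len[[2L]] / (2 * pi * n_turns)
  if (kappa * R >= 1) {
    stopf("loop_curvature_amp %.3g is unreachable: %d turn(s) over %.0f um allow at most %.3g 1/um",
          kappa, n_turns, len[[2L]], 1 / R)
  }
  rho <- kappa * R^2
  cc <- sqrt(R^2 - rho^2)
  phi <- params$loop_tilt_deg * pi / 180
  w <- c(cos(phi), 0, sin(phi))                  # tilted loop-stack axis
  v_raw <- c(1, 0, 0) - sum(c(1, 0, 0) * w) * w
  v <- if (sqrt(sum(v_raw^2)) < 1e-8) c(0, 1, 0) else unit(v_raw)
  u <- vcross(v, w)
  tt <- seq(0, 2 * pi * n_turns, length.out = n_seg[[2L]])
  loop <- outer(rho * cos(tt), u) + outer(rho * sin(tt), v) + outer(cc * R * tt / R, w)
  loop <- sweep(loop, 2L, loop[1L, ])
  loop <- sweep(loop, 2L, ant[n_a, ], `+`)

  # hindgut: tighter coil about the body axis (straight if no turns)
  n_h <- n_seg[[3L]]
  if (params$hindgut_coil_turns > 0) {
    R2 <- len[[3L]] / (2 * pi * params$hindgut_coil_turns)
    rho2 <- 0.5 * R2
    c2 <- sqrt(R2^2 - rho2^2)
    t2 <- seq(0, 2 * pi * params$hindgut_coil_turns, length.out = n_h)
    hind <- cbind(c2 * t2, rho2 * cos(t2), rho2 * sin(t2))
  } else {
    hind <- cbind(seq(0, len[[3L]], length.out = n_h), 0, 0)
  }
  hind <- sweep(hind, 2L, hind[1L, ])
  hind <- sweep(hind, 2L, loop[nrow(loop), ], `+`)

  pts <- rbind(ant, loop[-1L, , drop = FALSE], hind[-1L, , drop = FALSE])
  i_start <- n_a
  i_end <- n_a + nrow(loop) - 1L

  if (params$noise_sd > 0) {
    pts <- pts + with_seed(seed, smooth_displacement(nrow(pts), params$noise_sd))
  }

  # R3: arclength midpoint of the loop region (on the final, noisy curve)
  seg <- row_norms(diff(pts))
  s <- c(0, cumsum(seg))
  mid_s <- (s[i_start] + s[i_end]) / 2
  i_r3 <- which.min(abs(s - mid_s))

  centreline(pts, specimen_id = specimen_id, sex = sex, batch = batch,
             landmarks = list(loop_start = pts[i_start, ],
                              loop_end = pts[i_end, ],
                              R3 = pts[i_r3, ]))
}

# Smooth random displacement: independent spline interpolations of control
# values, one per coordinate, scaled to the requested amplitude.
smooth_displacement <- function(n, amp, n_ctrl = 15L) {
  u <- seq(0, 1, length.out = n)
  ctrl <- seq(0, 1, length.out = n_ctrl)
  vapply(1:3, function(j) {
    spline(ctrl, rnorm(n_ctrl, sd = amp), xout = u)$y
  }, numeric(n))
}

#' Generate a synthetic cohort
#'
#' Draws `2 * n_per_group` specimens (one set per sex) with mild
#' mean-preserving specimen-level jitter around each group's parameters, so
#' the group means of curvature amplitude, tilt, length and radius equal the
#' specified values. Covariates (gonad and crop volumes) are drawn
#' log-normal with sex-specific means, correlated with gut length through a
#' shared specimen factor; batches are assigned cyclically.
#'
#' @param spec a [cohort_spec()].
#' @param n_points points per centreline.
#' @return list of specimens, each a list with `centreline`, `params` (the
#'   realized specimen parameters) and `meta` (one-row data frame: sex,
#'   batch, gut_length, gonad_volume, crop_volume, plus the true generator
#'   values for recovery tests).
#' @export
generate_cohort <- function(spec, n_points = 1000L) {
  stopifnot(inherits(spec, "cohort_spec"))
  sexes <- rep(c("female", "male"), each = spec$n_per_group)
  batches <- rep_len(spec$batch_labels, length(sexes))
  out <- vector("list", length(sexes))
  for (i in seq_along(sexes)) {
    sx <- sexes[i]
    base <- if (sx == "female") spec$female else spec$male
    sd_i <- derive_seed(spec$seed, i)
    jit <- with_seed(sd_i, rnorm(7L))
    z <- jit[1L]  # shared specimen factor
    p_i <- base
    p_i$total_length <- base$total_length * (1 + 0.05 * z + 0.03 * jit[2L])
    # clip the jittered amplitude to what the loop geometry can realize
    amp_max <- 0.93 * 2 * pi * base$loop_count /
      (REGION_FRACTIONS[["loops"]] * p_i$total_length)
    p_i$loop_curvature_amp <- min(amp_max,
                                  base$loop_curvature_amp * (1 + 0.05 * jit[3L]))
    p_i$loop_tilt_deg <- max(0, base$loop_tilt_deg + 2 * jit[4L])
    p_i$tube_radius_mean <- base$tube_radius_mean * (1 + 0.05 * jit[5L])
    id <- sprintf("%s_%02d", sx, ((i - 1L) %% spec$n_per_group) + 1L)
    cl <- generate_centreline(p_i, seed = derive_seed(sd_i, 1L),
                              n_points = n_points, specimen_id = id,
                              sex = sx, batch = batches[i])
    gv_mean <- if (sx == "female") 3e7 else 6e6
    gonad <- exp(log(gv_mean) + 0.25 * z + 0.2 * jit[6L])
    crop <- exp(log(2e7) + 0.15 * z + 0.2 * jit[7L])
    out[[i]] <- list(
      centreline = cl, params = p_i,
      meta = data.frame(specimen_id = id, sex = sx, batch = batches[i],
                        gut_length = curve_length(parameterize(cl)),
                        gonad_volume = gonad, crop_volume = crop,
                        true_length = p_i$total_length,
                        true_amp = p_i$loop_curvature_amp,
                        true_tilt = p_i$loop_tilt_deg,
                        true_radius = p_i$tube_radius_mean))
  }
  out
}

#' Cohort metadata table
#'
#' @param cohort output of [generate_cohort()].
#' @return data frame with one row per specimen.
#' @export
cohort_metadata <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "meta"))
}

#' Generate a watertight tube mesh around a centreline
#'
#' Sweeps a ring of `n_ring` vertices along the curve using parallel
#' transport frames (no frame twist), closing both ends with triangle fans.
#' Warns when the requested radius approaches the local radius of
#' curvature, where the tube would self-intersect.
#'
#' @param x a [centreline()] or `param_curve`.
#' @param radius tube radius: a scalar, a per-point vector, or a radius
#'   [scalar_profile()].
#' @param n_ring vertices per cross-section ring (default 16).
#' @return a [surface_mesh()].
#' @export
generate_tube_mesh <- function(x, radius, n_ring = 16L) {
  p <- parameterize(x)
  pts <- p$points
  n <- nrow(pts)
  if (inherits(radius, "scalar_profile")) {
    radius <- approx(radius$s, radius$values, p$s, rule = 2, ties = "ordered")$y
  }
  radius <- rep_len(as.numeric(radius), n)
  if (any(!is.finite(radius)) || any(radius <= 0)) stopf("radius must be positive everywhere")
  tang <- rbind(pts[2L, ] - pts[1L, ], pts[3:n, , drop = FALSE] - pts[1:(n - 2L), , drop = FALSE],
                pts[n, ] - pts[n - 1L, ])
  tang <- tang / row_norms(tang)
  # discrete curvature check: turning angle per unit length
  ang <- acos(pmin(1, pmax(-1, rowSums(tang[-n, ] * tang[-1L, ]))))
  seg <- row_norms(diff(pts))
  kappa_disc <- ang / pmax(seg, 1e-12)
  # rolling median so an isolated tangent kink does not trip the alarm
  if (length(kappa_disc) >= 5L) kappa_disc <- stats::runmed(kappa_disc, 5L)
  if (any(radius[-n] * kappa_disc > 0.8)) {
    warnf("tube radius reaches %.0f%% of the local radius of curvature; the tube may self-intersect",
          100 * max(radius[-n] * kappa_disc))
  }
  # parallel transport an initial normal along the curve
  nrm <- matrix(0, n, 3L)
  ref <- if (abs(tang[1L, 1L]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  nrm[1L, ] <- unit(vcross(tang[1L, ], ref))
  for (i in 2:n) {
    Rm <- rotation_between(tang[i - 1L, ], tang[i, ])
    nrm[i, ] <- unit(drop(Rm %*% nrm[i - 1L, ]))
  }
  ang_ring <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  verts <- matrix(0, n * n_ring + 2L, 3L)
  for (i in seq_len(n)) {
    b <- vcross(tang[i, ], nrm[i, ])
    ring <- pts[rep(i, n_ring), ] +
      radius[i] * (outer(cos(ang_ring), nrm[i, ]) + outer(sin(ang_ring), b))
    verts[((i - 1L) * n_ring + 1L):(i * n_ring), ] <- ring
  }
  verts[n * n_ring + 1L, ] <- pts[1L, ]   # anterior cap centre
  verts[n * n_ring + 2L, ] <- pts[n, ]    # posterior cap centre
  faces <- matrix(0L, 2L * (n - 1L) * n_ring + 2L * n_ring, 3L)
  fi <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq_len(n_ring)) {
      j2 <- if (j == n_ring) 1L else j + 1L
      a1 <- (i - 1L) * n_ring + j; a2 <- (i - 1L) * n_ring + j2
      b1 <- i * n_ring + j; b2 <- i * n_ring + j2
      faces[fi + 1L, ] <- c(a1, b1, a2)
      faces[fi + 2L, ] <- c(a2, b1, b2)
      fi <- fi + 2L
    }
  }
  cap1 <- n * n_ring + 1L; cap2 <- n * n_ring + 2L
  for (j in seq_len(n_ring)) {
    j2 <- if (j == n_ring) 1L else j + 1L
    faces[fi + 1L, ] <- c(cap1, j, j2)
    faces[fi + 2L, ] <- c(cap2, (n - 1L) * n_ring + j2, (n - 1L) * n_ring + j)
    fi <- fi + 2L
  }
  surface_mesh(verts, faces, organ_name = "gut_tube",
               specimen_id = if (is.null(p$specimen_id)) "synthetic" else p$specimen_id)
}

#' Generate a synthetic intensity trace
#'
#' A smooth regional mean (baseline plus a Gaussian elevation centred at
#' `intensity_peak_pos`, the R3 anchor) plus stationary AR noise with the
#' requested coefficients and innovation standard deviation.
#'
#' @param length_points number of samples along the gut.
#' @param params a [generator_params()].
#' @param seed simulation seed.
#' @param specimen_id identifier.
#' @return an intensity [scalar_profile()] on \[0, 1\] with the anchor set
#'   to the peak position.
#' @export
generate_intensity_trace <- function(length_points, params, seed = 1L,
                                     specimen_id = "synthetic") {
  validate_params(params)
  if (!is_count(length_points) || length_points < 10L) {
    stopf("length_points must be an integer >= 10")
  }
  u <- seq(0, 1, length.out = length_points)
  m <- 0.2 + params$intensity_peak_amp *
    exp(-(u - params$intensity_peak_pos)^2 / (2 * 0.08^2))
  noise <- if (params$ar_noise_sd > 0) {
    with_seed(seed, as.numeric(arima.sim(
      model = if (length(params$ar_coeffs)) list(ar = params$ar_coeffs) else list(),
      n = length_points, sd = params$ar_noise_sd)))
  } else rep(0, length_points)
  scalar_profile(u, m + noise, "intensity", L = 1,
                 specimen_id = specimen_id,
                 anchor = params$intensity_peak_pos)
}

#' Generate a pair of organ meshes at a controlled separation
#'
#' Two congruent meshes whose true minimal surface separation equals `gap`.
#' Spheres are built with their poles on the separation axis, so the
#' minimal vertex-to-vertex distance equals the gap exactly; boxes face
#' each other with matching vertices.
#'
#' @param gap surface separation in micrometres (>= 0).
#' @param shape `"sphere"` or `"box"`.
#' @param seed seed for the azimuthal phase jitter of spheres.
#' @param size sphere radius or box half-side (micrometres).
#' @param n resolution (rings/segments for spheres).
#' @return list of two [surface_mesh()]es.
#' @export
generate_organ_pair <- function(gap, shape = c("sphere", "box"), seed = 1L,
                                size = 20, n = 12L) {
  shape <- match.arg(shape)
  if (!is.numeric(gap) || gap < 0) stopf("gap must be >= 0")
  if (shape == "sphere") {
    phase <- with_seed(seed, runif(1, 0, 2 * pi))
    m1 <- uv_sphere(size, n, centre = c(0, 0, 0), phase = phase)
    m2 <- uv_sphere(size, n, centre = c(2 * size + gap, 0, 0), phase = phase)
  } else {
    m1 <- box_mesh(size, centre = c(0, 0, 0))
    m2 <- box_mesh(size, centre = c(2 * size + gap, 0, 0))
  }
  m1$organ_name <- "organ_a"; m2$organ_name <- "organ_b"
  list(m1, m2)
}

# UV sphere with poles on the x axis (so a vertex sits exactly at +-r).
uv_sphere <- function(r, n, centre = c(0, 0, 0), phase = 0) {
  th <- seq(0, pi, length.out = n + 1L)[2:n]    # interior rings
  ph <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)] + phase
  verts <- rbind(c(r, 0, 0),
                 do.call(rbind, lapply(th, function(t) {
                   cbind(r * cos(t), r * sin(t) * cos(ph), r * sin(t) * sin(ph))
                 })),
                 c(-r, 0, 0))
  nr <- length(th)
  ring <- function(i) 1L + (i - 1L) * n + seq_len(n)  # vertex ids of ring i
  faces <- list()
  r1 <- ring(1L)
  faces[[1L]] <- cbind(1L, r1, c(r1[-1L], r1[1L]))
  for (i in seq_len(nr - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    a2 <- c(a[-1L], a[1L]); b2 <- c(b[-1L], b[1L])
    faces[[length(faces) + 1L]] <- rbind(cbind(a, b, a2), cbind(a2, b, b2))
  }
  rl <- ring(nr); last <- nrow(verts)
  faces[[length(faces) + 1L]] <- cbind(last, c(rl[-1L], rl[1L]), rl)
  surface_mesh(sweep(verts, 2L, centre, `+`), do.call(rbind, faces),
               organ_name = "sphere")
}

box_mesh <- function(half, centre = c(0, 0, 0)) {
  s <- half
  v <- as.matrix(expand.grid(x = c(-s, s), y = c(-s, s), z = c(-s, s)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(sweep(v, 2L, centre, `+`), f, organ_name = "box")
}
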