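# End-to-end orchestration: simulate a cohort, extract geometry, run the
# shape statistics, functional comparison, proximity mapping and intensity
# profiles, and write per-stage artifacts with a reproducibility manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable documented by its
#' default: cohort settings, stage toggles, and numerical parameters
#' (pseudolandmark count, Taylor-neighbourhood fraction, smoothing cutoff,
#' discretization grid, permutation iterations, contact threshold).
#'
#' @return a named list; edit fields and pass to [run_pipeline()], or save
#'   as YAML.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_per_group = 10L,
    n_points = 600L,
    batch_labels = c("batch1", "batch2"),
    stages = c("simulate", "geometry", "morphometrics", "compare",
               "proximity", "profiles"),
    k_landmarks = 500L,
    delta_frac = 0.05,
    cutoff = 0.3,
    n_grid = 200L,
    n_eval = 600L,
    iterations = 1000L,
    contact_threshold = 5,
    mds_dim = 3L,
    n_bins = 40L,
    ar_order = 1L,
    input_dir = NULL
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  cfg <- utils::modifyList(default_config(), config)
  unknown <- setdiff(names(config), names(default_config()))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (cfg$delta_frac <= 0 || cfg$delta_frac >= 0.5) stopf("delta_frac out of range (0, 0.5)")
  if (cfg$cutoff <= 0 || cfg$cutoff >= 1) stopf("cutoff out of range (0, 1)")
  cfg
}

log_info <- function(fmt, ...) message(sprintf(paste0("[gutmorph] ", fmt), ...))

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated cohort (or
#' on centrelines read from `input_dir` as CSV files plus a `cohort.csv`
#' metadata table): geometry (curvature, torsion, tilt, lengths),
#' morphometrics (GPA, PCA, Procrustes ANOVA with RRPP, pairwise tests),
#' functional comparison (curvature distances, MDS, ellipsoids, location
#' test), proximity (gut tube vs a synthetic neighbour organ) and intensity
#' profiles (binning and curvature correlation). Writes per-stage CSV/JSON
#' artifacts into `out_dir` together with `manifest.json` listing every
#' output file with its checksum, the seed and the effective parameters.
#' Identical configuration and seed reproduce identical outputs.
#'
#' @param config configuration list or YAML path; see [default_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("gutmorph_run_")) {
  cfg <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, path)
    path
  }
  stage_on <- function(s) s %in% cfg$stages

  ## simulate (or load) ------------------------------------------------------
  if (!is.null(cfg$input_dir)) {
    meta_path <- file.path(cfg$input_dir, "cohort.csv")
    if (!file.exists(meta_path)) stopf("missing input file: %s", meta_path)
    meta <- read.csv(meta_path)
    cohort <- lapply(seq_len(nrow(meta)), function(i) {
      path <- file.path(cfg$input_dir, paste0(meta$specimen_id[i], ".csv"))
      if (!file.exists(path)) stopf("missing input file: %s", path)
      list(centreline = read_centreline(path, specimen_id = meta$specimen_id[i],
                                        sex = meta$sex[i], batch = meta$batch[i]),
           meta = meta[i, , drop = FALSE])
    })
    log_info("loaded %d centrelines from %s", length(cohort), cfg$input_dir)
  } else {
    spec <- cohort_spec(n_per_group = cfg$n_per_group,
                        batch_labels = cfg$batch_labels, seed = cfg$seed)
    cohort <- generate_cohort(spec, n_points = cfg$n_points)
    log_info("simulated cohort: %d specimens", length(cohort))
    if (stage_on("simulate")) {
      dir.create(file.path(out_dir, "centrelines"), showWarnings = FALSE)
      for (sp in cohort) {
        files <- c(files, write_centreline(
          sp$centreline,
          file.path(out_dir, "centrelines", paste0(sp$centreline$specimen_id, ".csv"))))
      }
    }
  }
  meta <- cohort_metadata(cohort)
  emit_csv(meta, "cohort.csv")
  res$meta <- meta
  curves <- lapply(cohort, function(sp) parameterize(sp$centreline))
  names(curves) <- meta$specimen_id

  ## geometry ----------------------------------------------------------------
  if (stage_on("geometry")) {
    t0 <- Sys.time()
    geo <- lapply(curves, function(p) {
      kt <- curvature_torsion(p, delta_frac = cfg$delta_frac,
                              n_eval = cfg$n_eval, cutoff = cfg$cutoff)
      loop <- subset_by_landmarks(p, "loop_start", "loop_end")
      loop_kt <- curvature_torsion(loop, delta_frac = cfg$delta_frac,
                                   n_eval = cfg$n_eval, cutoff = cfg$cutoff)
      list(curvature = kt$curvature, torsion = kt$torsion,
           norm_curvature = normalize_by_length(kt$curvature),
           loop_norm_curvature = normalize_by_length(loop_kt$curvature),
           loop_mean_curvature = mean(loop_kt$curvature$values),
           tilt = tilt_angle(p, loop),
           length = p$L, loop_length = loop$L)
    })
    res$geometry <- geo
    summ <- data.frame(specimen_id = meta$specimen_id, sex = meta$sex,
                       gut_length = vapply(geo, `[[`, 1, "length"),
                       loop_length = vapply(geo, `[[`, 1, "loop_length"),
                       loop_mean_curvature = vapply(geo, `[[`, 1, "loop_mean_curvature"),
                       tilt_deg = vapply(geo, `[[`, 1, "tilt"))
    emit_csv(summ, "geometry_summary.csv")
    emit_csv(profile_table(lapply(geo, `[[`, "norm_curvature")), "curvature_profiles.csv")
    res$geometry_summary <- summ
    log_info("geometry stage done (%.1fs)", as.numeric(Sys.time() - t0, units = "secs"))
  }

  ## morphometrics -----------------------------------------------------------
  if (stage_on("morphometrics")) {
    t0 <- Sys.time()
    configs <- lapply(curves, resample_equal, k = cfg$k_landmarks)
    aligned <- gpa_align(configs)
    res$aligned <- aligned
    pca <- shape_pca(aligned)
    res$pca <- pca
    emit_csv(data.frame(specimen_id = meta$specimen_id, sex = meta$sex,
                        pca$scores[, seq_len(min(5L, ncol(pca$scores))), drop = FALSE]),
             "pca_scores.csv")
    form <- if (length(unique(meta$batch)) > 1L) {
      ~ sex + gonad_volume + crop_volume + gut_length + batch
    } else {
      ~ sex + gonad_volume + crop_volume + gut_length
    }
    anova <- procrustes_anova_rrpp(aligned, form, meta,
                                   iterations = cfg$iterations,
                                   seed = derive_seed(cfg$seed, 21L))
    res$anova <- anova
    emit_csv(as.data.frame(anova), "procrustes_anova.csv")
    pw <- pairwise_group_comparison(
      aligned, meta$sex, meta,
      null_formula = if (length(unique(meta$batch)) > 1L) ~ batch else ~ 1,
      iterations = cfg$iterations, seed = derive_seed(cfg$seed, 22L))
    res$pairwise <- pw
    emit_csv(data.frame(group_a = rep(pw$groups, each = length(pw$groups)),
                        group_b = rep(pw$groups, length(pw$groups)),
                        distance = as.numeric(pw$distance),
                        p = as.numeric(pw$p)),
             "pairwise_comparisons.csv")
    log_info("morphometrics stage done (%.1fs)", as.numeric(Sys.time() - t0, units = "secs"))
  }

  ## functional comparison ---------------------------------------------------
  if (stage_on("compare")) {
    if (is.null(res$geometry)) stopf("stage 'compare' needs stage 'geometry'")
    t0 <- Sys.time()
    profs <- lapply(res$geometry, `[[`, "loop_norm_curvature")
    for (i in seq_along(profs)) profs[[i]]$specimen_id <- meta$specimen_id[i]
    dm <- distance_matrix(profs, relative = TRUE, n_grid = cfg$n_grid)
    res$distances <- dm
    emit_csv(as.data.frame(unclass(dm)), "curvature_distances.csv")
    emb <- mds_embed(dm, dim = cfg$mds_dim, seed = derive_seed(cfg$seed, 31L))
    res$mds <- emb
    emit_csv(data.frame(specimen_id = meta$specimen_id, sex = meta$sex,
                        emb$points, stress = emb$stress),
             "mds_embedding.csv")
    is_f <- meta$sex == "female"
    ells <- list(female = group_ellipsoid(emb$points[is_f, , drop = FALSE]),
                 male = group_ellipsoid(emb$points[!is_f, , drop = FALSE]))
    res$ellipsoids <- ells
    emit_json(lapply(ells, function(e) {
      list(centre = e$centre, radii = e$radii, axes = e$axes, level = e$level)
    }), "ellipsoids.json")
    lt <- location_test(emb$points[is_f, , drop = FALSE],
                        emb$points[!is_f, , drop = FALSE],
                        seed = derive_seed(cfg$seed, 32L))
    res$location <- lt
    emit_json(lt, "location_test.json")
    log_info("compare stage done (%.1fs): stress %.3f, location p %.4g [%s]",
             as.numeric(Sys.time() - t0, units = "secs"), emb$stress, lt$p, lt$test)
  }

  ## proximity ---------------------------------------------------------------
  if (stage_on("proximity")) {
    t0 <- Sys.time()
    prox <- vector("list", length(cohort))
    for (i in seq_along(cohort)) {
      p <- curves[[i]]
      coarse <- resample_curve(p, 120L)
      tube <- generate_tube_mesh(coarse, cohort[[i]]$meta$true_radius %||% 80,
                                 n_ring = 10L)
      # neighbour organ: a sphere placed off the R3 landmark
      r3 <- p$landmarks$R3 %||% p$points[round(nrow(p$points) / 2), ]
      organ <- uv_sphere(60, 10L, centre = r3 + c(0, 0, 200))
      organ$organ_name <- "neighbour"
      prox[[i]] <- centreline_proximity(p, tube, organ)
    }
    res$proximity <- prox
    calls <- contact_call(prox, threshold = cfg$contact_threshold)
    res$contacts <- calls
    emit_csv(data.frame(specimen_id = meta$specimen_id,
                        min_distance = vapply(prox, function(x) min(x$distance), 1),
                        contact = calls$contact),
             "proximity_contacts.csv")
    emit_json(calls[c("frequency", "n_contact", "n_total", "threshold")],
              "contact_frequency.json")
    log_info("proximity stage done (%.1fs): contact frequency %.2f",
             as.numeric(Sys.time() - t0, units = "secs"), calls$frequency)
  }

  ## intensity profiles ------------------------------------------------------
  if (stage_on("profiles")) {
    if (is.null(res$geometry)) stopf("stage 'profiles' needs stage 'geometry'")
    t0 <- Sys.time()
    traces <- lapply(seq_along(cohort), function(i) {
      base <- if (meta$sex[i] == "female") female_params() else male_params()
      generate_intensity_trace(200L, base, seed = derive_seed(cfg$seed, 100L + i),
                               specimen_id = meta$specimen_id[i])
    })
    binned_int <- align_and_bin(traces, n_bins = cfg$n_bins)
    curv_traces <- lapply(seq_along(cohort), function(i) {
      f <- res$geometry[[i]]$norm_curvature
      f$anchor <- 0.5
      f
    })
    binned_curv <- align_and_bin(curv_traces, n_bins = cfg$n_bins)
    res$binned_intensity <- binned_int
    res$binned_curvature <- binned_curv
    res$curv_int_r <- curvature_intensity_correlation(binned_curv, binned_int)
    emit_csv(as.data.frame(binned_int), "binned_intensity.csv")
    emit_csv(as.data.frame(binned_curv), "binned_curvature.csv")
    is_f <- meta$sex == "female"
    cs <- pairwise_profile_correlation(
      lapply(curv_traces[is_f], function(f) unit_normalize(f)),
      lapply(traces[is_f], function(f) unit_normalize(f)))
    res$correlations_female <- cs
    emit_csv(correlation_table(cs), "correlations_female.csv")
    emit_json(list(curvature_intensity_r = res$curv_int_r,
                   n_female_pairs = length(cs$coefficients)),
              "profile_summary.json")
    log_info("profiles stage done (%.1fs): binned r = %.3f",
             as.numeric(Sys.time() - t0, units = "secs"), res$curv_int_r)
  }

  ## manifest ----------------------------------------------------------------
  files <- unique(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gutmorph")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "stages")],
    stages = cfg$stages,
    outputs = lapply(files, function(f) {
      list(path = sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", out_dir), "/?"),
                      "", f),
           md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  log_info("run complete: %d artifacts in %s", length(files) + 1L, out_dir)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
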