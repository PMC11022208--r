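#' Pipeline configuration
#'
#' One document holding every stage's parameters, validated against the known
#' schema (unknown keys are rejected).  The resolved configuration is written
#' next to the outputs of every run.
#'
#' @param outdir Output directory.
#' @param rng_seed Master seed; stage seeds derive from it.
#' @param ... Stage overrides; see Details.
#'
#' @details Sections and defaults:
#' * `input`: `mode` (`"phantom"` or `"files"`), `ct`, `kidney_mask` (paths,
#'   `files` mode), `phantom` (a [phantom_spec()] override list).
#' * `preprocess`: `clip_lo` (-256), `clip_hi` (512), `resample_shape`
#'   (`NULL` = keep grid).
#' * `extract`: `elem` (5, 9, 9), `largest_cc` (FALSE).
#' * `mesh`: `sigma_vox` (0.8), `iso` (0.5).
#' * `skeleton`: `step_size` (5), `wave_count` (2).
#' * `trajectory`: `spacing_mm` (4), `vfov_deg` (60).
#' * `render`: `preset` ("customlight"), `resolution` (128), `n_frames` (12).
#' * `metrics`: `enabled` (FALSE), `d_out` (64), `subset_size` (8),
#'   `n_subsets` (10).
#' @export
pipeline_config <- function(outdir, rng_seed = 1L, ...) {
  defaults <- list(
    outdir = outdir, rng_seed = as.integer(rng_seed),
    input = list(mode = "phantom", ct = NULL, kidney_mask = NULL,
                 phantom = list()),
    preprocess = list(clip_lo = -256, clip_hi = 512, resample_shape = NULL),
    extract = list(elem = c(5L, 9L, 9L), largest_cc = FALSE),
    mesh = list(sigma_vox = 0.8, iso = 0.5),
    skeleton = list(step_size = 5L, wave_count = 2L),
    trajectory = list(spacing_mm = 4, vfov_deg = 60),
    render = list(preset = "customlight", resolution = 128L, n_frames = 12L),
    metrics = list(enabled = FALSE, d_out = 64L, subset_size = 8L,
                   n_subsets = 10L))
  overrides <- list(...)
  for (key in names(overrides)) {
    if (!key %in% names(defaults))
      stopf("unknown pipeline config section '%s'", key)
    if (is.list(defaults[[key]])) {
      bad <- setdiff(names(overrides[[key]]), names(defaults[[key]]))
      if (length(bad))
        stopf("unknown key '%s' in config section '%s'", bad[1], key)
      defaults[[key]] <- utils::modifyList(defaults[[key]], overrides[[key]])
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  structure(defaults, class = "uro_pipeline_config")
}

#' Run the full virtual-ureteroscopy pipeline
#'
#' Executes preprocess, extract, mesh, skeletonize, trajectory and render
#' stages (plus optional metrics), writing each stage's outputs under
#' `config$outdir` and returning a manifest listing every produced file with
#' its stage, parameters and md5 hash.  Stages whose outputs already exist
#' are resumed from the intermediates when `resume = TRUE`, so deleting one
#' stage's outputs and re-running regenerates exactly those files.  A stage
#' failure halts the run with the stage name in the error.
#'
#' @param config A [pipeline_config()].
#' @param resume Reuse existing stage outputs (default `TRUE`).
#' @return Manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, resume = TRUE) {
  stopifnot(inherits(config, "uro_pipeline_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  t_start <- Sys.time()
  log_stage <- function(stage, msg)
    message(sprintf("[uroscope] %-10s %s", stage, msg))
  rel <- function(p) {
    pre <- paste0(out, "/")
    ifelse(startsWith(p, pre), substring(p, nchar(pre) + 1L), p)
  }
  add <- function(stage, files, params) {
    manifest[[stage]] <<- list(files = as.list(rel(files)),
                               md5 = as.list(unname(tools::md5sum(files))),
                               params = params)
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  path <- function(...) file.path(out, ...)
  cfg_save <- unclass(config)
  cfg_save$outdir <- NULL  # keep the resolved config path-independent
  jsonlite::write_json(cfg_save, path("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  # -- input ----------------------------------------------------------------
  ct_path <- path("ct.nii.gz"); lab_path <- path("labels.nii.gz")
  run_stage("input", {
    if (config$input$mode == "phantom") {
      if (!resume || !file.exists(ct_path) || !file.exists(lab_path)) {
        spec <- do.call(phantom_spec, utils::modifyList(
          list(rng_seed = config$rng_seed), config$input$phantom))
        ph <- make_phantom(spec)
        write_volume(ph$ct, ct_path)
        write_volume(ph$labels, lab_path)
        jsonlite::write_json(list(points = ph$centerline$points,
                                  branch = ph$centerline$branch),
                             path("centerline.json"), digits = NA)
        log_stage("input", "phantom generated")
      } else log_stage("input", "phantom reused")
      add("input", c(ct_path, lab_path), config$input$phantom)
    } else {
      if (is.null(config$input$ct) || !file.exists(config$input$ct))
        stopf("input CT file not found: %s", config$input$ct %||% "<missing>")
      if (is.null(config$input$kidney_mask) || !file.exists(config$input$kidney_mask))
        stopf("kidney mask file not found: %s",
              config$input$kidney_mask %||% "<missing>")
      ct_path <<- config$input$ct; lab_path <<- config$input$kidney_mask
      add("input", c(ct_path, lab_path), list(mode = "files"))
    }
  })

  # -- preprocess -----------------------------------------------------------
  norm_path <- path("norm.nii.gz")
  run_stage("preprocess", {
    if (!resume || !file.exists(norm_path)) {
      ct <- read_volume(ct_path)
      v <- clip_normalize(ct, config$preprocess$clip_lo, config$preprocess$clip_hi)
      if (!is.null(config$preprocess$resample_shape))
        v <- resample_to_shape(v, config$preprocess$resample_shape)
      write_volume(v, norm_path)
      log_stage("preprocess", "normalized")
    } else log_stage("preprocess", "reused")
    add("preprocess", norm_path, config$preprocess)
  })

  # -- extract --------------------------------------------------------------
  cs_path <- path("cs.nii.gz")
  run_stage("extract", {
    if (!resume || !file.exists(cs_path)) {
      v <- read_volume(norm_path)
      lab <- read_labelmap(lab_path)
      kidney <- uro_labelmap(array(as.integer(lab$data > 0L), dim(lab$data)),
                             lab$spacing, lab$origin,
                             semantics = c(background = 0L, foreground = 1L))
      if (!is.null(config$preprocess$resample_shape))
        kidney <- resample_to_shape(kidney, config$preprocess$resample_shape)
      cs <- extract_collecting_system(v, kidney,
                                      structuring_element(config$extract$elem),
                                      largest_cc = config$extract$largest_cc)
      write_volume(cs, cs_path)
      log_stage("extract", sprintf("%d collecting-system voxels", sum(cs$data)))
    } else log_stage("extract", "reused")
    add("extract", cs_path, config$extract)
  })

  # -- mesh -----------------------------------------------------------------
  mesh_path <- path("cs.ply")
  run_stage("mesh", {
    if (!resume || !file.exists(mesh_path)) {
      cs <- read_labelmap(cs_path)
      m <- marching_cubes(smooth_binary(cs, config$mesh$sigma_vox),
                          config$mesh$iso)
      write_mesh(m, mesh_path)
      log_stage("mesh", sprintf("%d vertices", nrow(m$vertices)))
    } else log_stage("mesh", "reused")
    add("mesh", mesh_path, config$mesh)
  })

  # -- skeletonize ----------------------------------------------------------
  skel_path <- path("skel.json")
  run_stage("skeletonize", {
    if (!resume || !file.exists(skel_path)) {
      m <- read_mesh(mesh_path)
      sk <- skeletonize(m, wave_params(config$skeleton$step_size,
                                       config$skeleton$wave_count,
                                       rng_seed = config$rng_seed))
      write_skeleton(sk, skel_path)
      log_stage("skeletonize", sprintf("%d nodes", nrow(sk$nodes)))
    } else log_stage("skeletonize", "reused")
    add("skeletonize", skel_path, config$skeleton)
  })

  # -- trajectory -----------------------------------------------------------
  poses_path <- path("poses.json")
  run_stage("trajectory", {
    if (!resume || !file.exists(poses_path)) {
      sk <- read_skeleton(skel_path)
      poses <- sample_trajectory(sk, config$trajectory$spacing_mm,
                                 config$trajectory$vfov_deg)
      write_poses(poses, poses_path)
      log_stage("trajectory", sprintf("%d poses", length(poses)))
    } else log_stage("trajectory", "reused")
    add("trajectory", poses_path, config$trajectory)
  })

  # -- render ---------------------------------------------------------------
  frames_dir <- path("frames")
  run_stage("render", {
    dir.create(frames_dir, showWarnings = FALSE)
    poses <- read_poses(poses_path)
    n <- min(config$render$n_frames, length(poses))
    sel <- unique(round(seq(1, length(poses), length.out = n)))
    frame_paths <- file.path(frames_dir,
                             sprintf("frame_%03d.png", seq_along(sel)))
    todo <- !resume | !file.exists(frame_paths)
    if (any(todo)) {
      m <- read_mesh(mesh_path)
      cfg <- lighting_preset(config$render$preset)
      res <- rep(config$render$resolution, length.out = 2)
      for (i in which(todo))
        write_image(render(m, poses[[sel[i]]], cfg, res), frame_paths[i])
      log_stage("render", sprintf("%d frames rendered", sum(todo)))
    } else log_stage("render", "reused")
    add("render", frame_paths, config$render)
  })

  # -- metrics (optional) ---------------------------------------------------
  if (isTRUE(config$metrics$enabled)) {
    metrics_path <- path("metrics.json")
    run_stage("metrics", {
      poses <- read_poses(poses_path)
      m <- read_mesh(mesh_path)
      n <- min(config$render$n_frames, length(poses))
      sel <- unique(round(seq(1, length(poses), length.out = n)))
      res <- rep(config$render$resolution, length.out = 2)
      main <- lapply(sel, function(i)
        render(m, poses[[i]], lighting_preset(config$render$preset), res))
      base <- lapply(sel, function(i)
        render(m, poses[[i]], lighting_preset("baseline"), res))
      sty <- make_style_domain(main, rng_seed = config$rng_seed)
      fm <- extract_features_rp(main, config$metrics$d_out)
      fb <- extract_features_rp(base, config$metrics$d_out)
      fs <- extract_features_rp(sty, config$metrics$d_out)
      vals <- list(
        kid_preset = kid(fm, fs, config$metrics$subset_size,
                         config$metrics$n_subsets, config$rng_seed),
        kid_baseline = kid(fb, fs, config$metrics$subset_size,
                           config$metrics$n_subsets, config$rng_seed),
        fid_preset = fid(fm, fs), fid_baseline = fid(fb, fs))
      jsonlite::write_json(vals, metrics_path, auto_unbox = TRUE, digits = NA)
      add("metrics", metrics_path, config$metrics)
      log_stage("metrics", sprintf("kid %.4f (preset) vs %.4f (baseline)",
                                   vals$kid_preset, vals$kid_baseline))
    })
  }

  manifest$run <- list(seed = config$rng_seed,
                       elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                       units = "secs")))
  mpath <- path("manifest.json")
  save_manifest <- manifest
  save_manifest$run$elapsed_s <- NULL  # keep the manifest byte-reproducible
  jsonlite::write_json(save_manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
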