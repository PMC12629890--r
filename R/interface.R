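#' Read / write recording-site tables
#'
#' CSV schema: `trajectory_id, depth_mm, x, y, z, label`.  Errors name the
#' offending column.  All indices in file formats are 0-based where indices
#' occur; depths are signed mm with the planned target at 0 (negative above
#' the target).
#'
#' @param path CSV path.
#' @return A [recording_sites()] table (read) or `path` (write).
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("sites file not found: ", path)
  recording_sites(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_sites
#' @param sites a [recording_sites()] table.
#' @export
write_sites <- function(sites, path) {
  sites <- recording_sites(sites)
  write.csv(as.data.frame(sites), path, row.names = FALSE)
  invisible(path)
}

#' Read / write NRMS tables
#'
#' CSV schema: `trajectory_id, depth_mm, nrms` (one row per depth, depths
#' ordered within trajectory).
#'
#' @param path CSV path.
#' @return Named list of [nrms_sequence()] per trajectory (read) or `path`
#'   (write).
#' @export
read_nrms <- function(path) {
  if (!file.exists(path)) stop("NRMS file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("trajectory_id", "depth_mm", "nrms")) {
    if (!col %in% names(df)) stop("NRMS table is missing column: ", col)
  }
  out <- lapply(split(df, df$trajectory_id), function(d) {
    d <- d[order(d$depth_mm), ]
    nrms_sequence(d$trajectory_id[1], d$depth_mm, d$nrms)
  })
  out[unique(df$trajectory_id)]
}

#' @rdname read_nrms
#' @param nrms a single [nrms_sequence()] or a list of them.
#' @export
write_nrms <- function(nrms, path) {
  if (inherits(nrms, "nrms_sequence")) nrms <- list(nrms)
  df <- do.call(rbind, lapply(nrms, function(s) {
    data.frame(trajectory_id = s$trajectory_id, depth_mm = s$depth,
               nrms = s$nrms)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Resolved configuration of a full run (simulate/load, classify, coalign,
#' evaluate).  Every run writes a manifest echoing this configuration plus
#' package and R versions, sufficient to reproduce the run.
#'
#' @param mesh_path path to the STN mesh (STL/PLY/VTK); `NULL` when
#'   simulating.
#' @param sites_path path to the sites CSV; `NULL` when simulating or when
#'   classification will produce the labels.
#' @param nrms_path optional path to a precomputed NRMS CSV.
#' @param output_dir run directory (created if needed).
#' @param simulate `NULL`, or a named list of [make_scene()] arguments — the
#'   scene then provides mesh, sites and NRMS.
#' @param classifier `"labels"` (use labels already present in the sites
#'   table), `"threshold"` (NRMS threshold `tau`) or a path to a trained
#'   classifier checkpoint JSON.
#' @param tau NRMS threshold used when `classifier = "threshold"`.
#' @param n_baseline NRMS baseline depth count (when computing NRMS from
#'   raw segments; informational otherwise).
#' @param max_shift_norm,scale_range co-alignment bounds.
#' @param epsilon,multi_start co-alignment options, see [coalign()].
#' @param voxel_size Dice voxelisation resolution (mm).
#' @param seed run seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mesh_path = NULL, sites_path = NULL,
                            nrms_path = NULL, output_dir = tempfile("run"),
                            simulate = NULL, classifier = "labels", tau = 1.5,
                            n_baseline = 5L, max_shift_norm = 3.0,
                            scale_range = c(0.8, 1.2), epsilon = 1e-6,
                            multi_start = FALSE, voxel_size = 0.2, seed = 1L) {
  structure(list(mesh_path = mesh_path, sites_path = sites_path,
                 nrms_path = nrms_path, output_dir = output_dir,
                 simulate = simulate, classifier = classifier, tau = tau,
                 n_baseline = as.integer(n_baseline),
                 max_shift_norm = max_shift_norm,
                 scale_range = as.numeric(scale_range), epsilon = epsilon,
                 multi_start = isTRUE(multi_start), voxel_size = voxel_size,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full co-alignment pipeline
#'
#' Stages: (1) obtain a scene — either simulate one or load mesh + sites
#' (and optionally NRMS) from files; (2) obtain per-depth labels — from the
#' sites table, from NRMS thresholding, or from a trained sequence
#' classifier; (3) co-align; (4) evaluate (fraction of STN sites inside the
#' mesh before/after, costs).  Stage boundaries are files: every stage
#' output is written to `output_dir` along with `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `sites`, `mesh`, `result`
#'   (the [coalign()] output), `metrics` and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # ---- stage 1: scene ----
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (is.null(args$seed)) args$seed <- config$seed
    scene <- do.call(make_scene, args)
    mesh <- scene$mesh
    sites <- scene$sites
    nrms <- scene$nrms
    write_mesh(mesh, out("mesh.stl"))
    write_sites(sites, out("sites.csv"))
    write_nrms(nrms, out("nrms.csv"))
    say("simulate: scene seed %d, %d sites", scene$seed, nrow(sites))
  } else {
    if (is.null(config$mesh_path)) stop("stage simulate/load: no mesh_path and no simulate block")
    mesh <- read_mesh(config$mesh_path)
    if (is.null(config$sites_path)) stop("stage load: sites_path is required")
    sites <- read_sites(config$sites_path)
    nrms <- if (!is.null(config$nrms_path)) read_nrms(config$nrms_path) else NULL
    scene <- NULL
    say("load: %d sites, mesh with %d faces", nrow(sites), nrow(mesh$faces))
  }

  # ---- stage 2: labels ----
  if (identical(config$classifier, "labels")) {
    say("classify: using labels supplied with the sites table")
  } else {
    if (is.null(nrms)) stop("stage classify: classifier requires NRMS input")
    preds <- if (identical(config$classifier, "threshold")) {
      lapply(nrms, classify_threshold, tau = config$tau)
    } else {
      model <- read_classifier(config$classifier)
      lapply(nrms, classify_sequence, model = model)
    }
    pred_df <- do.call(rbind, lapply(preds, function(p) {
      data.frame(trajectory_id = p$trajectory_id, depth_mm = p$depth,
                 label = p$label,
                 probability = if (is.null(p$probability)) NA_real_ else p$probability)
    }))
    write.csv(pred_df, out("predictions.csv"), row.names = FALSE)
    key_sites <- paste(sites$trajectory_id, round(sites$depth_mm, 6))
    key_pred <- paste(pred_df$trajectory_id, round(pred_df$depth_mm, 6))
    hit <- match(key_sites, key_pred)
    if (anyNA(hit)) stop("stage classify: predictions do not cover all site depths")
    sites$label <- as.integer(pred_df$label[hit])
    say("classify: %s -> %d STN depths of %d",
        if (identical(config$classifier, "threshold")) sprintf("threshold tau=%.2f", config$tau)
        else "sequence model", sum(sites$label), nrow(sites))
  }

  # ---- stage 3: co-alignment ----
  bounds <- coalignment_bounds(config$max_shift_norm, config$scale_range)
  result <- coalign(sites, mesh, bounds, epsilon = config$epsilon,
                    multi_start = config$multi_start)
  say("coalign: shift (%.3f, %.3f, %.3f) mm, scale %.4f, cost %.4g -> %.4g",
      result$shift[1], result$shift[2], result$shift[3], result$scale,
      result$cost_initial, result$cost_final)
  jsonlite::write_json(
    list(shift = result$shift, scale = result$scale,
         cost_initial = result$cost_initial, cost_final = result$cost_final,
         objective_final = result$objective_final,
         n_evaluations = result$n_evaluations, converged = result$converged,
         scale_center = result$scale_center,
         bounds = unclass(result$bounds), convention = result$convention),
    out("coalignment.json"), digits = NA, auto_unbox = TRUE)

  # ---- stage 4: evaluation ----
  transformed <- apply_coalignment(sites, mesh, result)
  write_sites(transformed$sites, out("sites_coaligned.csv"))
  write_mesh(transformed$mesh, out("mesh_scaled.stl"))
  metrics <- list(
    fraction_inside_before = if (any(sites$label == 1L)) fraction_inside(sites, mesh) else NA_real_,
    fraction_inside_after = if (any(sites$label == 1L)) {
      fraction_inside(transformed$sites, transformed$mesh)
    } else NA_real_,
    cost_initial = result$cost_initial,
    cost_final = result$cost_final,
    voxel_size = config$voxel_size)
  say("evaluate: fraction inside %.3f -> %.3f",
      metrics$fraction_inside_before, metrics$fraction_inside_after)
  jsonlite::write_json(metrics, out("metrics.json"), digits = NA, auto_unbox = TRUE)

  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("stncoalign")),
                   r_version = R.version.string,
                   seed = config$seed)
  jsonlite::write_json(manifest, out("manifest.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  writeLines(log_lines, out("run.log"))
  invisible(list(sites = sites, mesh = mesh, result = result,
                 metrics = metrics, scene = scene,
                 output_dir = config$output_dir))
}

#' Re-run a pipeline from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param output_dir optional new output directory (defaults to the one in
#'   the manifest).
#' @return See [run_pipeline()].
#' @export
run_from_manifest <- function(manifest_path, output_dir = NULL) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- m$config
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (!is.null(cfg$scale_range)) cfg$scale_range <- as.numeric(cfg$scale_range)
  if (!is.null(cfg$simulate)) cfg$simulate <- as.list(cfg$simulate)
  run_pipeline(do.call(pipeline_config, cfg))
}
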