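config_schema <- list(
  scan_id = NULL, seed = NULL, out_dir = NULL,
  poses = c("spacing_deg", "cone_deg"),
  camera = c("pixel_pitch_um", "width_px", "height_px", "magnification",
             "focus_distance_mm"),
  scene = c("sphere_radius_mm", "sphere_center_mm", "pin", "pin_radius_mm",
            "bound_radius_mm", "texture_amplitude", "texture_length_mm"),
  stack = c("n_slices", "step_um", "aperture_mm"),
  edof = c("window_px", "median_radius"),
  mask = c("min_area_px", "close_radius_px"),
  hull = c("grid_n", "half_extent_mm")
)

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) against the pipeline
#' schema; unknown keys are rejected with an error naming the
#' offending key, and missing values are filled with defaults.
#'
#' @param config A named list, or the path of a YAML file.
#' @return The validated, default-completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in names(config)) {
    if (!key %in% names(config_schema))
      stop("config error: unknown key '", key, "'")
    sub <- config_schema[[key]]
    if (!is.null(sub))
      for (k2 in names(config[[key]]))
        if (!k2 %in% sub)
          stop("config error: unknown key '", key, ".", k2, "'")
  }
  defaults <- list(
    scan_id = "scan", seed = 1L, out_dir = "scan_out",
    poses = list(spacing_deg = 90, cone_deg = 15),
    camera = list(pixel_pitch_um = 5.5, width_px = 96L, height_px = 96L,
                  magnification = 0.11, focus_distance_mm = 100),
    scene = list(sphere_radius_mm = 1.5, sphere_center_mm = c(0, 0, 0),
                 pin = FALSE, pin_radius_mm = 0.15, bound_radius_mm = 2.5,
                 texture_amplitude = 0.35, texture_length_mm = 0.25),
    stack = list(n_slices = 7, step_um = 700, aperture_mm = 10),
    edof = list(window_px = 9, median_radius = 2),
    mask = list(min_area_px = 50, close_radius_px = 2),
    hull = list(grid_n = 64, half_extent_mm = NA))
  out <- defaults
  for (key in names(config)) {
    if (is.null(config_schema[[key]])) out[[key]] <- config[[key]]
    else for (k2 in names(config[[key]])) out[[key]][[k2]] <- config[[key]][[k2]]
  }
  if (is.na(out$hull$half_extent_mm))
    out$hull$half_extent_mm <- out$scene$bound_radius_mm
  out
}

scene_from_config <- function(cfg) {
  tex <- list(amplitude = cfg$scene$texture_amplitude,
              length_mm = cfg$scene$texture_length_mm)
  solids <- list(solid_sphere(cfg$scene$sphere_center_mm,
                              cfg$scene$sphere_radius_mm, texture = tex))
  if (isTRUE(cfg$scene$pin)) {
    top <- cfg$scene$sphere_center_mm - c(0, 0, cfg$scene$sphere_radius_mm * 0.8)
    bot <- c(top[1], top[2], -cfg$scene$bound_radius_mm + cfg$scene$pin_radius_mm)
    solids <- c(solids, list(solid_capsule(top, bot, cfg$scene$pin_radius_mm)))
  }
  scene(solids, bound_radius_mm = cfg$scene$bound_radius_mm)
}

camera_from_config <- function(cfg) {
  camera_model(pixel_pitch_um = cfg$camera$pixel_pitch_um,
               width_px = cfg$camera$width_px, height_px = cfg$camera$height_px,
               magnification = cfg$camera$magnification,
               focus_distance_mm = cfg$camera$focus_distance_mm)
}

#' Run the automated scan-to-measurement pipeline
#'
#' Executes pose-program generation, synthetic scanning, EDOF
#' compositing, masking, visual-hull reconstruction and morphometry
#' for every accessible pose, writing all artifacts under one scan
#' directory with a machine-readable \code{manifest.json}.  A rerun
#' skips poses whose status is already \code{done}, and the whole run
#' is deterministic given the configuration (which includes the seed).
#'
#' @param config Configuration list or YAML path (see
#'   \code{\link{validate_config}}).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the manifest, the hull mesh path and
#'   the morphometry report.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- validate_config(config)
  t0 <- Sys.time()
  log_line <- function(...) if (!quiet) {
    message(sprintf("[%6.2fs] ", as.numeric(Sys.time() - t0)), sprintf(...))
  }
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE) else
    list(scan_id = cfg$scan_id, config = cfg, poses = list())

  program <- apply_exclusion(generate_pose_program(cfg$poses$spacing_deg),
                             cfg$poses$cone_deg)
  write_pose_csv(program, file.path(out_dir, "poses.csv"))
  scn <- scene_from_config(cfg)
  cam <- camera_from_config(cfg)
  cal <- stack_calibration(cfg$stack$n_slices, cfg$stack$step_um,
                           beta = (cfg$stack$step_um / 1000) / cam$focus_distance_mm)
  write_calibration(cal, file.path(out_dir, "calibration.yaml"))

  acc <- program$poses[program$poses$accessible, ]
  log_line("pose program: %d poses, %d accessible", nrow(program$poses), nrow(acc))
  masks <- vector("list", nrow(acc))
  poses <- vector("list", nrow(acc))
  n_failed <- 0
  for (k in seq_len(nrow(acc))) {
    idx <- acc$index[k]
    key <- sprintf("pose_%04d", idx)
    poses[[k]] <- pose(acc$tilt_deg[k], acc$rot_deg[k], index = idx)
    masked_path <- file.path(out_dir, sprintf("%s_masked.png", key))
    rec <- manifest$poses[[key]]
    if (!is.null(rec) && identical(rec$status, "done") &&
        file.exists(masked_path)) {
      rgba <- png::readPNG(masked_path)
      masks[[k]] <- rgba[, , 4] > 0.5
      next
    }
    status <- tryCatch({
      fr <- render_pose_stack(scn, poses[[k]], cam, cfg$stack$n_slices,
                              cfg$stack$step_um, "front",
                              seed = cfg$seed, aperture_mm = cfg$stack$aperture_mm)
      bk <- render_pose_stack(scn, poses[[k]], cam, cfg$stack$n_slices,
                              cfg$stack$step_um, "back",
                              seed = cfg$seed, aperture_mm = cfg$stack$aperture_mm)
      ef <- compose_edof(fr, cal, window_px = cfg$edof$window_px,
                         median_radius = cfg$edof$median_radius)
      eb <- compose_edof(bk, cal, window_px = cfg$edof$window_px,
                         median_radius = cfg$edof$median_radius)
      sm <- segment_backlight(luminance(eb$image),
                              min_area_px = cfg$mask$min_area_px,
                              close_radius_px = cfg$mask$close_radius_px)
      png::writePNG(apply_alpha(ef$image, sm), masked_path)
      masks[[k]] <- sm$mask
      "done"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    if (status != "done") n_failed <- n_failed + 1
    manifest$poses[[key]] <- list(index = idx, tilt_deg = acc$tilt_deg[k],
                                  rot_deg = acc$rot_deg[k],
                                  masked_path = masked_path, status = status)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    log_line("pose %d/%d (%s): %s", k, nrow(acc), key, status)
  }
  ok <- !vapply(masks, is.null, logical(1))
  if (!any(ok)) stop("all poses failed; no hull to carve")
  log_line("carving %d^3 grid from %d masks", cfg$hull$grid_n, sum(ok))
  grid <- carve(masks[ok], poses[ok], cam,
                voxel_grid(cfg$hull$grid_n, cfg$hull$half_extent_mm))
  mesh <- extract_surface(grid)
  hull_path <- file.path(out_dir, "hull.obj")
  write_obj(mesh, hull_path)
  report <- measure_mesh(mesh)
  utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  log_line("hull: %d faces, %.3f cm^3, %.3f cm^2", nrow(mesh$faces),
           report$volume_cm3, report$surface_area_cm2)
  invisible(list(manifest = manifest, hull_path = hull_path,
                 report = report, exit_status = as.integer(n_failed > 0)))
}
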