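# Shared synthetic-scanner fixtures.  Image sizes are kept small so
# the whole suite runs quickly; the acceptance tests use the same
# constructions at the sizes stated in the vignette.

# camera with a given field of view (mm) at a given image width
test_camera <- function(width_px = 128, fov_mm = 6.4, z_f = 100) {
  camera_model(width_px = width_px, height_px = width_px,
               magnification = 5.5e-3 * width_px / fov_mm,
               focus_distance_mm = z_f)
}

# the 26 directions of the 3x3x3 neighborhood, as poses
poses_26 <- function() {
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  lapply(seq_len(nrow(dirs)), function(i)
    pose(asin(dirs[i, 3]) * 180 / pi,
         (atan2(dirs[i, 2], dirs[i, 1]) * 180 / pi) %% 360,
         index = i - 1L))
}

sphere_scene <- function(radius_mm = 3, bound = radius_mm + 0.2)
  scene(list(solid_sphere(c(0, 0, 0), radius_mm, albedo = 0.6)),
        bound_radius_mm = bound)

# textured plane tilted against the viewing axis of pose (0, 0)
tilted_plane_scene <- function(tilt_deg = 40, radius_mm = 2.5) {
  a <- tilt_deg * pi / 180
  scene(list(solid_disc(c(0, 0, 0), c(cos(a), 0, sin(a)), radius_mm,
                        albedo = 0.6,
                        texture = list(amplitude = 0.35, length_mm = 0.3))),
        bound_radius_mm = radius_mm + 0.1)
}

# back-light scan -> silhouette masks for a list of poses
scan_masks <- function(scn, poses, cam, n_slices = 7, step_um = 1000) {
  cal <- stack_calibration(n_slices, step_um,
                           beta = (step_um / 1000) / cam$focus_distance_mm)
  lapply(poses, function(p) {
    bk <- render_pose_stack(scn, p, cam, n_slices, step_um, "back",
                            aperture_mm = 10)
    list(mask = segment_backlight(compose_edof(bk, cal)$image),
         gt = bk$gt$silhouette)
  })
}

# intensity-weighted blob centroids (u = col, v = row) above a threshold
blob_centroids <- function(img, thr = 0.4, floor_val = 0.05) {
  g <- if (length(dim(img)) == 3)
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3] else img
  lab <- EBImage::bwlabel(g > thr)
  t(vapply(seq_len(max(lab)), function(l) {
    w <- (g - floor_val) * (lab == l)
    c(u = sum(col(g) * w) / sum(w), v = sum(row(g) * w) / sum(w))
  }, numeric(2)))
}
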