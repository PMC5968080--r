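test_that("back-light silhouette of a centered sphere matches the analytic disc", {
  cam <- test_camera(width_px = 128, fov_mm = 6.4)
  scn <- sphere_scene(1.5, bound = 2)
  st <- render_pose_stack(scn, pose(30, 45), cam, n_slices = 1,
                          step_um = 500, "back", aperture_mm = 0)
  r_px <- 1.5 * cam$magnification / (cam$pixel_pitch_um / 1000)
  area <- sum(st$gt$silhouette)
  expect_lt(abs(sqrt(area / pi) - r_px), 1)
  # silhouette ground truth equals the thresholded back render, pixel-exact
  expect_identical(st$slices[[1]][, , 1] < 0.5, st$gt$silhouette)
})

test_that("ground-truth depth at the image center is camera distance minus radius", {
  cam <- test_camera(width_px = 96, fov_mm = 6.4)
  scn <- sphere_scene(1.5, bound = 2)
  st <- render_pose_stack(scn, pose(0, 0), cam, n_slices = 1,
                          step_um = 500, "back", aperture_mm = 0)
  ctr <- round(cam$principal_point_px)
  z <- st$gt$depth[ctr[2], ctr[1]]
  expect_lt(abs(z - (st$gt$camera_distance_mm - 1.5)) /
              (st$gt$camera_distance_mm - 1.5), 0.005)
})

test_that("a single pinhole slice equals the all-in-focus render", {
  cam <- test_camera(width_px = 64, fov_mm = 6.4)
  scn <- sphere_scene(1.5, bound = 2)
  st <- render_pose_stack(scn, pose(10, 200), cam, n_slices = 1,
                          step_um = 500, "front", seed = 5, aperture_mm = 0)
  expect_identical(st$slices[[1]], st$gt$sharp)
})

test_that("rendering is bit-identical across runs for a fixed seed", {
  cam <- test_camera(width_px = 64, fov_mm = 6.4)
  scn <- scene(list(solid_sphere(c(0.3, 0, 0.2), 1.2),
                    solid_capsule(c(0, 0, -1), c(0, 0, -2.4), 0.15)),
               bound_radius_mm = 2.6)
  a <- render_pose_stack(scn, pose(25, 30), cam, 5, 800, "front", seed = 42)
  b <- render_pose_stack(scn, pose(25, 30), cam, 5, 800, "front", seed = 42)
  expect_identical(a$slices, b$slices)
  d <- render_pose_stack(scn, pose(25, 30), cam, 5, 800, "front", seed = 43)
  expect_false(identical(a$slices, d$slices))
})

test_that("focus stacks have increasing rail positions and consistent shapes", {
  cam <- test_camera(width_px = 48, fov_mm = 6.4)
  st <- render_pose_stack(sphere_scene(1.5, bound = 2), pose(-45, 120),
                          cam, 6, 700, "front")
  expect_identical(length(st$slices), 6L)
  expect_true(all(diff(st$rail_positions_mm) > 0))
  expect_true(all(vapply(st$slices, function(s)
    identical(dim(s), c(48L, 48L, 3L)), logical(1))))
  expect_true(all(vapply(st$slices, function(s)
    min(s) >= 0 && max(s) <= 1, logical(1))))
})

test_that("rendered dot-grid scale follows the rail perspective model", {
  # the fixed target seen by the advancing camera: the image scale of
  # slice i relative to the reference must equal z_f / (z_f - step *
  # (i - ref)); measured per-slice scales must match within 0.2%
  z_f <- 50; step_mm <- 0.5
  cam <- camera_model(width_px = 192, height_px = 192,
                      magnification = 5.5e-3 * 192 / 9,
                      focus_distance_mm = z_f)
  ts <- render_target_stack(cam, n_slices = 21, step_um = 1000 * step_mm,
                            grid_pitch_mm = 0.9, dot_radius_mm = 0.12)
  ref <- ts$ref_index
  dots <- lapply(ts$slices, disc3d:::dot_centroids)
  pp <- cam$principal_point_px
  for (i in c(1, 6, 16, 21)) {
    model_q <- z_f / (z_f - step_mm * (i - ref))
    q <- disc3d:::refine_scale(dots[[ref]], dots[[i]], pp, model_q,
                               tol_px = 6)
    expect_lt(abs(q - model_q) / model_q, 0.002)
  }
  # and the fitted projective coefficient reproduces step / z_f
  cal <- calibrate_from_target(ts, 0.9)
  expect_lt(abs(cal$beta - step_mm / z_f) / (step_mm / z_f), 0.002)
})

test_that("make_scan writes one subdirectory per accessible pose", {
  dir <- withr::local_tempdir()
  cam <- test_camera(width_px = 32, fov_mm = 6.4)
  prog <- apply_exclusion(generate_pose_program(90), 15)
  man <- make_scan(sphere_scene(1.5, bound = 2), prog, cam, dir,
                   n_slices = 5, step_um = 700, write_stacks = TRUE)
  expect_identical(nrow(man), 4L)  # 6 poses minus the two poles
  expect_identical(length(list.dirs(dir, recursive = FALSE)), 4L)
  st <- read_stack_tiff(man$front_path[1], step_um = 700)
  expect_identical(length(st$slices), 5L)
  # empty program errors
  none <- apply_exclusion(generate_pose_program(90), 90)
  expect_error(make_scan(sphere_scene(1.5, bound = 2), none, cam, dir),
               "accessible")
})
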