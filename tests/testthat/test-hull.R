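test_that("a single view carves the silhouette's generalized cylinder", {
  cam <- test_camera(width_px = 64, fov_mm = 8)
  # disc mask from a real back render of a sphere
  scn <- sphere_scene(2, bound = 2.4)
  st <- render_pose_stack(scn, pose(0, 0), cam, 1, 500, "back",
                          aperture_mm = 0)
  g <- carve(list(st$gt$silhouette), list(pose(0, 0)), cam,
             voxel_grid(48, 3))
  occ <- g$occupancy
  # every occupied voxel projects into the silhouette; the carved set is
  # (approximately) constant along the viewing axis (+x for pose (0,0))
  counts <- apply(occ, 1, sum)
  expect_true(all(counts > 0))
  expect_lt(diff(range(counts)) / max(counts), 0.1)
  # empty masks remove everything
  g0 <- carve(list(matrix(FALSE, 64, 64)), list(pose(0, 0)), cam,
              voxel_grid(24, 3))
  expect_identical(sum(g0$occupancy), 0L)
  expect_error(carve(list(), list(), cam), "poses")
})

test_that("carved sphere hull contains the truth and approximates its volume", {
  cam <- test_camera(width_px = 96, fov_mm = 9)
  scn <- sphere_scene(3, bound = 3.3)
  poses <- poses_26()
  masks <- lapply(poses, function(p)
    render_pose_stack(scn, p, cam, 1, 500, "back", aperture_mm = 0)$gt$silhouette)
  grid <- carve(masks, poses, cam, voxel_grid(80, 4))
  va <- 4 / 3 * pi * 27
  vol <- grid_volume(grid)
  expect_lt(vol, va * 1.05)
  expect_gt(vol, va * 0.98)
  # containment: no interior voxel deeper than the sampling margin is carved
  ctr <- disc3d:::voxel_centers(grid)
  margin <- grid$voxel_mm * sqrt(3) / 2 +
    object_pixel_size(cam$pixel_pitch_um, cam$magnification) / 1000
  deep <- rowSums(ctr^2) < (3 - margin)^2
  expect_identical(sum(deep & !as.vector(grid$occupancy)), 0L)
  # monotonicity: more views never increase the hull
  v_sub <- grid_volume(carve(masks[1:9], poses[1:9], cam, voxel_grid(80, 4)))
  expect_gte(v_sub, vol)
  # surface extraction: watertight, volume matches the voxel volume
  mesh <- extract_surface(grid)
  expect_true(is_watertight(mesh))
  expect_lt(abs(mesh_volume(mesh) * 1000 - vol) / vol, 1e-9)
  expect_lt(abs(mesh_volume(mesh) * 1000 - va) / va, 0.06)
})

test_that("extract_surface handles a single voxel and rejects empty grids", {
  g <- voxel_grid(8, 2)
  g$occupancy[] <- FALSE
  expect_error(extract_surface(g), "empty")
  g$occupancy[4, 5, 3] <- TRUE
  mesh <- extract_surface(g)
  expect_identical(nrow(mesh$faces), 12L)
  expect_true(is_watertight(mesh))
  expect_equal(mesh_volume(mesh) * 1000, g$voxel_mm^3, tolerance = 1e-12)
  expect_gt(disc3d:::signed_volume_mm3(mesh), 0)  # outward orientation
})

test_that("diagonal voxel contacts are healed into a manifold surface", {
  g <- voxel_grid(6, 2)
  g$occupancy[] <- FALSE
  g$occupancy[2, 2, 2] <- TRUE
  g$occupancy[3, 3, 2] <- TRUE   # edge contact in the xy plane
  g$occupancy[5, 5, 5] <- TRUE
  g$occupancy[4, 4, 4] <- TRUE   # corner contact (vertex only)
  mesh <- extract_surface(g)
  expect_true(is_watertight(mesh))
})

test_that("the hull cannot recover the concave groove of a ring solid", {
  # closed ring of capsules circumscribing a torus (R = 2.2, r = 0.8):
  # the visual hull fills concave regions, so its volume must exceed
  # the analytic torus volume 2 pi^2 R r^2
  R <- 2.2; r <- 0.8; N <- 16
  sag <- R * (1 - cos(pi / N))
  ang <- seq(0, 2 * pi, length.out = N + 1)
  pts <- cbind(R * cos(ang), R * sin(ang), 0)
  caps <- lapply(seq_len(N), function(i)
    solid_capsule(pts[i, ], pts[i + 1, ], r + sag))
  scn <- scene(caps, bound_radius_mm = R + r + sag + 0.1)
  cam <- test_camera(width_px = 96, fov_mm = 9)
  poses <- poses_26()
  masks <- lapply(poses, function(p)
    render_pose_stack(scn, p, cam, 1, 500, "back", aperture_mm = 0)$gt$silhouette)
  grid <- carve(masks, poses, cam, voxel_grid(64, 3.5))
  expect_gt(grid_volume(grid), 2 * pi^2 * R * r^2)
})

test_that("OBJ meshes round-trip through write and read", {
  mesh <- mesh_icosphere(5, 2)
  f <- withr::local_tempfile(fileext = ".obj")
  write_obj(mesh, f)
  back <- read_obj(f)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-7)
  expect_identical(back$faces, mesh$faces)
  expect_equal(mesh_volume(back), mesh_volume(mesh), tolerance = 1e-6)
})
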