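test_that("focus measure is zero on constant images and peaks on edges", {
  expect_true(all(focus_measure(matrix(0.37, 64, 64)) == 0))
  step <- cbind(matrix(0, 64, 32), matrix(1, 64, 32))
  fmap <- focus_measure(step, window_px = 5)
  peak_cols <- apply(fmap[10:54, ], 1, which.max)
  expect_true(all(peak_cols %in% 32:33))
  expect_error(focus_measure(matrix(0, 8, 8), window_px = 4), "odd")
  expect_error(focus_measure(matrix(0, 8, 8), window_px = 11), "larger")
})

test_that("per-pixel argmax finds the sharp slice of a textured plane", {
  cam <- test_camera(width_px = 96, fov_mm = 5)
  scn <- tilted_plane_scene(0, radius_mm = 2.2)  # frontal plane
  n <- 9
  st <- render_pose_stack(scn, pose(0, 0), cam, n, 1000, "front",
                          seed = 3, aperture_mm = 10)
  fm <- vapply(st$slices, focus_measure, matrix(0, 96, 96))
  arg <- apply(fm, c(1, 2), which.max)
  fg <- st$gt$silhouette
  # erode the margin where the blurred background bleeds in
  fg[1:6, ] <- FALSE; fg[91:96, ] <- FALSE
  fg[, 1:6] <- FALSE; fg[, 91:96] <- FALSE
  expect_gt(mean(arg[fg] == st$ref_index), 0.99)
})

test_that("rescale_to_reference is an exact identity at s = 1 and fixes the center", {
  img <- matrix(runif(64 * 64), 64, 64)
  cal <- stack_calibration(5, 1000, beta = 0.02)
  expect_identical(rescale_to_reference(img, cal$ref_index, cal, c(32, 32)),
                   img)
  # a dot at the principal point stays put under s = 0.5-ish scaling
  img2 <- matrix(0, 65, 65); img2[33, 33] <- 1
  cal2 <- stack_calibration(3, 1000, beta = 0.5, ref_index = 1)
  s <- slice_scale(3, cal2)  # 0.5
  out <- rescale_to_reference(img2, 3, cal2, c(33, 33))
  expect_equal(which(out == max(out), arr.ind = TRUE)[1, ],
               c(row = 33, col = 33))
})

test_that("rescaling moves off-center features by the scale factor", {
  # two dots 100 px apart centered on the principal point, s = 1/1.1
  img <- matrix(0, 128, 128)
  img[64, 14] <- 1; img[64, 114] <- 1
  img <- as.matrix(EBImage::gblur(img, 1.5))
  cal <- stack_calibration(21, 1000, beta = 0.01)
  out <- rescale_to_reference(img, cal$ref_index + 10, cal, c(64, 64))
  ctr <- blob_centroids(out / max(out), thr = 0.3, floor_val = 0)
  expect_identical(nrow(ctr), 2L)
  expect_equal(abs(diff(ctr[, "u"])), 100 * 100 / 110, tolerance = 0.01)
})

test_that("EDOF of a degenerate stack reproduces the slice", {
  cam <- test_camera(width_px = 64, fov_mm = 6.4)
  st <- render_pose_stack(sphere_scene(1.5, bound = 2), pose(0, 0), cam,
                          1, 500, "front", seed = 2, aperture_mm = 0)
  sl <- st$slices[[1]]
  stack5 <- st
  stack5$slices <- rep(list(sl), 5)
  stack5$rail_positions_mm <- (0:4) * 0.5
  ed <- compose_edof(stack5, stack_calibration(5, 500, beta = 0))
  expect_equal(ed$image, sl, tolerance = 1e-12)
})

test_that("EDOF depth map recovers the tilted plane within tolerance", {
  cam <- test_camera(width_px = 128, fov_mm = 6.4)
  n <- 15
  st <- render_pose_stack(tilted_plane_scene(40), pose(0, 0), cam, n, 500,
                          "front", seed = 7, aperture_mm = 10)
  cal <- stack_calibration(n, 500, beta = 0.005)
  ed <- compose_edof(st, cal)
  gt <- st$gt$depth_index
  fg <- is.finite(gt) & gt >= 1 & gt <= n & !ed$depth$background
  expect_gt(sum(fg), 3000)
  err <- ed$depth$values[fg] - gt[fg]
  expect_lt(sqrt(mean(err^2)), 0.75)
  expect_gt(mean(abs(err) <= 1), 0.95)
})

test_that("EDOF output stays in range with no NaNs and flags background", {
  cam <- test_camera(width_px = 64, fov_mm = 6.4)
  st <- render_pose_stack(sphere_scene(1.5, bound = 2), pose(40, 10), cam,
                          7, 700, "front", seed = 1, aperture_mm = 10)
  ed <- compose_edof(st, stack_calibration(7, 700, beta = 0.007))
  expect_false(any(!is.finite(ed$image)))
  expect_true(min(ed$image) >= 0 && max(ed$image) <= 1)
  expect_true(all(ed$depth$values >= 1 & ed$depth$values <= 7))
  # background flag covers the true background beyond the halo that the
  # focus-measure window spreads around the silhouette edge
  halo <- EBImage::dilate(st$gt$silhouette * 1, EBImage::makeBrush(11, "disc")) > 0.5
  expect_gt(mean(ed$depth$background[!halo]), 0.98)
  # shape mismatch and empty stacks error
  bad <- st; bad$slices[[2]] <- bad$slices[[2]][1:32, , ]
  expect_error(compose_edof(bad, stack_calibration(7, 700, beta = 0)),
               "shape")
  empty <- st; empty$slices <- list()
  expect_error(compose_edof(empty, stack_calibration(7, 700, beta = 0)),
               "empty|slices")
})
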